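"source","target"
"s1","s2"
"s1","s3"
"s1","s4"
"s1","s5"
"s1","s6"
"s1","s7"
"s1","s8"
"s2","s3"
"s2","s4"
"s2","s5"
"s2","s6"
"s2","s7"
"s2","s8"
"s3","s4"
"s3","s5"
"s3","s6"
"s3","s7"
"s3","s8"
"s4","s5"
"s4","s6"
"s4","s7"
"s4","s8"
"s5","s6"
"s5","s7"
"s5","s8"
"s6","s7"
"s6","s8"
"s7","s8"
"s9","s10"
"s9","s11"
"s9","s12"
"s9","s13"
"s10","s11"
"s10","s12"
"s10","s13"
"s11","s12"
"s11","s13"
"s12","s13"
"s14","s15"
"s14","s16"
"s14","s17"
"s14","s18"
"s14","s19"
"s14","s20"
"s15","s16"
"s15","s17"
"s15","s18"
"s15","s19"
"s15","s20"
"s16","s17"
"s16","s18"
"s16","s19"
"s16","s20"
"s17","s18"
"s17","s19"
"s17","s20"
"s18","s19"
"s18","s20"
"s19","s20"
"s21","s22"
"s21","s23"
"s21","s24"
"s21","s25"
"s21","s26"
"s21","s27"
"s22","s23"
"s22","s24"
"s22","s25"
"s22","s26"
"s22","s27"
"s23","s24"
"s23","s25"
"s23","s26"
"s23","s27"
"s24","s25"
"s24","s26"
"s24","s27"
"s25","s26"
"s25","s27"
"s26","s27"
"s28","s29"
"s28","s30"
"s28","s31"
"s28","s32"
"s28","s33"
"s29","s30"
"s29","s31"
"s29","s32"
"s29","s33"
"s30","s31"
"s30","s32"
"s30","s33"
"s31","s32"
"s31","s33"
"s32","s33"
"s34","s35"
"s34","s36"
"s34","s37"
"s34","s38"
"s34","s39"
"s34","s40"
"s35","s36"
"s35","s37"
"s35","s38"
"s35","s39"
"s35","s40"
"s36","s37"
"s36","s38"
"s36","s39"
"s36","s40"
"s37","s38"
"s37","s39"
"s37","s40"
"s38","s39"
"s38","s40"
"s39","s40"
"s1","m1_1"
"s2","m1_1"
"s3","m1_1"
"s4","m1_1"
"s5","m1_1"
"s6","m1_1"
"s7","m1_1"
"s8","m1_1"
"s9","m1_2"
"s10","m1_2"
"s11","m1_2"
"s12","m1_2"
"s13","m1_2"
"s14","m1_3"
"s15","m1_3"
"s16","m1_3"
"s17","m1_3"
"s18","m1_3"
"s19","m1_3"
"s20","m1_3"
"s21","m1_4"
"s22","m1_4"
"s23","m1_4"
"s24","m1_4"
"s25","m1_4"
"s26","m1_4"
"s27","m1_4"
"s28","m1_5"
"s29","m1_5"
"s30","m1_5"
"s31","m1_5"
"s32","m1_5"
"s33","m1_5"
"s34","m1_6"
"s35","m1_6"
"s36","m1_6"
"s37","m1_6"
"s38","m1_6"
"s39","m1_6"
"s40","m1_6"
"m1_1","m1_3"
"m1_1","m1_5"
"m1_3","m1_5"
"m1_2","m1_4"
"m1_2","m1_6"
"m1_4","m1_6"
"m1_1","m2_1"
"m1_2","m2_2"
"m1_3","m2_1"
"m1_4","m2_2"
"m1_5","m2_1"
"m1_6","m2_2"
"m2_1","m2_2"
"m2_1","apex"
"m2_2","apex"
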