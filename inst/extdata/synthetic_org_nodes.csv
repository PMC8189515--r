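"node_id","level"
"s1",1
"s2",1
"s3",1
"s4",1
"s5",1
"s6",1
"s7",1
"s8",1
"s9",1
"s10",1
"s11",1
"s12",1
"s13",1
"s14",1
"s15",1
"s16",1
"s17",1
"s18",1
"s19",1
"s20",1
"s21",1
"s22",1
"s23",1
"s24",1
"s25",1
"s26",1
"s27",1
"s28",1
"s29",1
"s30",1
"s31",1
"s32",1
"s33",1
"s34",1
"s35",1
"s36",1
"s37",1
"s38",1
"s39",1
"s40",1
"m1_1",2
"m1_2",2
"m1_3",2
"m1_4",2
"m1_5",2
"m1_6",2
"m2_1",3
"m2_2",3
"apex",4
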