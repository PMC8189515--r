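// Micro-step engine for the multilayer dosage contagion model.
//
// States: 0 = S (susceptible), 1 = I (adopted/promoting), 2 = R (removed,
// absorbing).  Each micro-step one listener is drawn uniformly from all
// nodes, a speaker uniformly from its neighbours (all layers pooled); the
// conferred dose enters the listener's rolling memory of the last T doses
// and the cumulative dose D is compared against the listener's threshold.
//
// Random variates come from five independent substreams seeded from a
// single master seed (thresholds, listener, speaker, dose, removal) so two
// graphs on the same node set see identical attempted transmission
// pathways (common random numbers).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

class SubStream {
 public:
  SubStream(uint64_t master, uint32_t stream_id) {
    std::seed_seq ss{static_cast<uint32_t>(master & 0xffffffffu),
                     static_cast<uint32_t>(master >> 32), stream_id,
                     0x9e3779b9u};
    eng_.seed(ss);
  }
  // uniform in [0, 1)
  double unif() { return (eng_() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in 0..n-1
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Box-Muller, no spare caching (stream state stays one-draw-per-call pair)
  double normal(double mean, double sd) {
    double u1;
    do {
      u1 = unif();
    } while (u1 <= 0.0);
    double u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1)) *
               std::cos(6.283185307179586 * u2);
    return mean + sd * z;
  }
  // truncation by resampling (preserves the conditional shape)
  double normal_min(double mean, double sd, double lo, bool strict) {
    for (;;) {
      double x = normal(mean, sd);
      if (strict ? (x > lo) : (x >= lo)) return x;
    }
  }

 private:
  std::mt19937_64 eng_;
};

enum StreamId : uint32_t {
  kThreshold = 0,
  kListener = 1,
  kSpeaker = 2,
  kDose = 3,
  kRemoval = 4
};

}  // namespace

// Per-node adoption thresholds d* ~ N(thr_mean, thr_sd) resampled to > 0,
// drawn in node-id order from the threshold substream.  Exposed so callers
// can reproduce exactly the thresholds a run with the same master seed uses.
// [[Rcpp::export]]
NumericVector sample_thresholds_cpp(int n, double thr_mean, double thr_sd,
                                    double master_seed) {
  SubStream rng(static_cast<uint64_t>(master_seed), kThreshold);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal_min(thr_mean, thr_sd, 0.0, true);
  return out;
}

// Truncated-normal sampler used for dose draws (resampled to >= 0).
// [[Rcpp::export]]
NumericVector sample_doses_cpp(int n, double dose_mean, double dose_sd,
                               double master_seed) {
  SubStream rng(static_cast<uint64_t>(master_seed), kDose);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal_min(dose_mean, dose_sd, 0.0, false);
  return out;
}

// Run the dosage model.
//
// offsets/neighbors: CSR adjacency, 0-based; offsets has length N+1.
// layer: per-node layer index (1 = staff).
// seeds: 0-based indices of initially adopted nodes.
// Returns per-epoch S/I/R counts (epoch = N micro-steps, epoch 0 = initial
// state), the peak concurrent I count with the micro-step it first occurred
// at, first micro-step of full consensus (I == N) and of extinction
// (I == 0), each -1 when never reached, the number of micro-steps executed
// and (optionally) the sampled thresholds.
// [[Rcpp::export]]
List dosage_run_cpp(IntegerVector offsets, IntegerVector neighbors,
                    IntegerVector layer, IntegerVector seeds, int T_mem,
                    double r, double thr_mean, double thr_sd,
                    double dose_mean, double dose_sd, bool manager_override,
                    bool si_mode, double max_micro_steps, bool early_stop,
                    double master_seed, bool return_thresholds) {
  const int N = layer.size();
  if (N <= 0) stop("empty graph");
  if (T_mem < 1) stop("memory window T must be >= 1");
  const double r_eff = si_mode ? 0.0 : r;

  const uint64_t master = static_cast<uint64_t>(master_seed);
  SubStream rng_thr(master, kThreshold);
  SubStream rng_listener(master, kListener);
  SubStream rng_speaker(master, kSpeaker);
  SubStream rng_dose(master, kDose);
  SubStream rng_removal(master, kRemoval);

  std::vector<double> thr(N);
  for (int i = 0; i < N; ++i)
    thr[i] = rng_thr.normal_min(thr_mean, thr_sd, 0.0, true);

  std::vector<int> state(N, 0);
  for (int k = 0; k < seeds.size(); ++k) state[seeds[k]] = 1;

  // rolling memory: T_mem doses per node, zero-initialised
  std::vector<double> mem(static_cast<size_t>(N) * T_mem, 0.0);
  std::vector<int> mem_pos(N, 0);

  int nI = seeds.size(), nR = 0;
  int nS = N - nI;

  const long long max_steps = static_cast<long long>(max_micro_steps);
  std::vector<int> trajS, trajI, trajR;
  trajS.reserve(max_steps / N + 2);
  trajI.reserve(max_steps / N + 2);
  trajR.reserve(max_steps / N + 2);

  int peak_I = nI;
  long long peak_step = 0;
  long long consensus_step = (nI == N) ? 0 : -1;
  long long extinct_step = (nI == 0) ? 0 : -1;

  long long step = 0;
  for (; step < max_steps; ++step) {
    if (step % N == 0) {
      trajS.push_back(nS);
      trajI.push_back(nI);
      trajR.push_back(nR);
      // no further transition is possible once I is empty, or once an
      // SI-mode run reaches full consensus
      if (early_stop && (nI == 0 || (si_mode && nI == N))) break;
    }

    const int listener = rng_listener.unif_int(N);
    const int deg = offsets[listener + 1] - offsets[listener];

    double dose = 0.0;
    if (deg > 0) {
      const int speaker = neighbors[offsets[listener] + rng_speaker.unif_int(deg)];
      if (state[speaker] == 1) {
        if (manager_override && layer[speaker] > layer[listener]) {
          dose = thr[listener];  // guarantees D >= d* for an S listener
        } else {
          dose = rng_dose.normal_min(dose_mean, dose_sd, 0.0, false);
        }
      }
    }
    // degree-0 listeners receive a null dose: memory still advances

    double* m = &mem[static_cast<size_t>(listener) * T_mem];
    m[mem_pos[listener]] = dose;
    mem_pos[listener] = (mem_pos[listener] + 1) % T_mem;
    double D = 0.0;
    for (int t = 0; t < T_mem; ++t) D += m[t];

    if (state[listener] == 0) {
      if (D >= thr[listener]) {
        state[listener] = 1;
        --nS;
        ++nI;
        if (nI > peak_I) {
          peak_I = nI;
          peak_step = step + 1;
        }
        if (nI == N && consensus_step < 0) consensus_step = step + 1;
      }
    } else if (state[listener] == 1 && D < thr[listener]) {
      if (r_eff > 0.0 && rng_removal.unif() < r_eff) {
        state[listener] = 2;
        --nI;
        ++nR;
        if (nI == 0 && extinct_step < 0) extinct_step = step + 1;
      }
    }
  }

  // final counts close the trajectory if the run ended mid-epoch
  if (trajS.empty() || trajS.back() != nS || trajI.back() != nI ||
      trajR.back() != nR) {
    trajS.push_back(nS);
    trajI.push_back(nI);
    trajR.push_back(nR);
  }

  List out = List::create(
      _["S"] = wrap(trajS), _["I"] = wrap(trajI), _["R"] = wrap(trajR),
      _["peak_I"] = peak_I, _["peak_step"] = static_cast<double>(peak_step),
      _["consensus_step"] = static_cast<double>(consensus_step),
      _["extinct_step"] = static_cast<double>(extinct_step),
      _["steps_done"] = static_cast<double>(step));
  if (return_thresholds) out["thresholds"] = wrap(thr);
  return out;
}
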