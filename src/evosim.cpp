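#include <Rcpp.h>
using namespace Rcpp;

// Engine for the behaviour-schedule evolutionary simulation.
//
// A genotype is a (behaviour, period) pair: behaviour 1 = cooperator,
// 0 = defector; period T >= 2. At intra-generational time point t an agent
// is active iff t % T == 0. Active agents are paired uniformly at random
// (one idles if the active count is odd) and play a one-shot prisoner's
// dilemma; payoffs accumulate over time points. Selection is a pairwise
// comparison process: a random focal agent adopts a random distinct model
// agent's genotype with probability 1 / (1 + exp(-s * (pi_m - pi_f))).
// Uses R's RNG so results are reproducible under set.seed().

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void play_generation_cpp(const std::vector<int>& beh,
                                const std::vector<int>& per,
                                int max_time_point,
                                double T, double R, double P, double S,
                                std::vector<double>& pay,
                                std::vector<int>& active) {
  const int n = (int)beh.size();
  std::fill(pay.begin(), pay.end(), 0.0);
  for (int t = 1; t <= max_time_point; ++t) {
    active.clear();
    for (int i = 0; i < n; ++i)
      if (t % per[i] == 0) active.push_back(i);
    const int m = (int)active.size();
    for (int k = m - 1; k > 0; --k) {
      int j = rand_below(k + 1);
      std::swap(active[k], active[j]);
    }
    for (int k = 0; k + 1 < m; k += 2) {
      int a = active[k], b = active[k + 1];
      if (beh[a] == 1 && beh[b] == 1)      { pay[a] += R; pay[b] += R; }
      else if (beh[a] == 1)                { pay[a] += S; pay[b] += T; }
      else if (beh[b] == 1)                { pay[a] += T; pay[b] += S; }
      else                                 { pay[a] += P; pay[b] += P; }
    }
  }
}

static bool homogeneous(const std::vector<int>& beh,
                        const std::vector<int>& per) {
  for (size_t i = 1; i < beh.size(); ++i)
    if (beh[i] != beh[0] || per[i] != per[0]) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_run_batch(int n_runs, int pop_size, int max_period,
                   int max_time_point,
                   double temptation, double reward, double punishment,
                   double sucker,
                   double s, int max_generations,
                   int events_per_generation,
                   Nullable<IntegerVector> init_behaviour = R_NilValue,
                   Nullable<IntegerVector> init_period = R_NilValue) {
  IntegerVector out_beh(n_runs), out_per(n_runs), out_gen(n_runs);
  LogicalVector out_fix(n_runs);

  std::vector<int> beh(pop_size), per(pop_size);
  std::vector<double> pay(pop_size);
  std::vector<int> active;
  active.reserve(pop_size);

  const bool fixed_init = init_behaviour.isNotNull();
  IntegerVector ib, ip;
  if (fixed_init) {
    ib = init_behaviour.get();
    ip = init_period.get();
    if (ib.size() != pop_size || ip.size() != pop_size)
      stop("init vectors must have length pop_size");
  }

  for (int run = 0; run < n_runs; ++run) {
    if (fixed_init) {
      for (int i = 0; i < pop_size; ++i) { beh[i] = ib[i]; per[i] = ip[i]; }
    } else {
      for (int i = 0; i < pop_size; ++i) {
        beh[i] = unif_rand() < 0.5 ? 1 : 0;
        per[i] = 2 + rand_below(max_period - 1);
      }
    }
    int gen = 0;
    bool fixed = homogeneous(beh, per);
    while (!fixed && gen < max_generations) {
      ++gen;
      play_generation_cpp(beh, per, max_time_point,
                          temptation, reward, punishment, sucker,
                          pay, active);
      for (int e = 0; e < events_per_generation; ++e) {
        int f = rand_below(pop_size);
        int m = rand_below(pop_size - 1);
        if (m >= f) ++m;
        double p = 1.0 / (1.0 + std::exp(-s * (pay[m] - pay[f])));
        if (unif_rand() < p) { beh[f] = beh[m]; per[f] = per[m]; }
      }
      fixed = homogeneous(beh, per);
      if (gen % 4096 == 0) checkUserInterrupt();
    }
    out_beh[run] = beh[0];
    out_per[run] = per[0];
    out_gen[run] = gen;
    out_fix[run] = fixed;
  }
  return List::create(_["behaviour"] = out_beh, _["period"] = out_per,
                      _["generations"] = out_gen, _["fixated"] = out_fix);
}
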