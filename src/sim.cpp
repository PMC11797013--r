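#include <Rcpp.h>
using namespace Rcpp;

// Forward-time homing gene drive generation loop.
//
// Allele 0 is the drive allele; susc[j] is the per-generation conversion rate
// of the drive acting on allele j in drive/j heterozygotes (susc[0] == 0).
// The genotype state G is the K x K outer-product matrix (column-major): each
// unordered heterozygote's mass is split across the two symmetric cells, so
// sum(G) == 1 and the full heterozygote frequency of pair (i, j) is 2*G[i,j].
//
// Arithmetic and RNG call order deliberately mirror the pure-R engine in
// R/core.R (long-double accumulation where R's sum()/rowSums() use it) so
// that identical seeds give identical trajectories in both engines.

static inline double sum_ld(const std::vector<double> &v) {
  long double acc = 0.0;
  for (size_t m = 0; m < v.size(); ++m) acc += v[m];
  return (double) acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_drive(NumericVector p0, NumericVector susc,
                                 double fitness_cost, double exposure,
                                 double dominance, double inbreeding,
                                 double pop_size, int generations,
                                 bool postzygotic, bool stochastic,
                                 bool multinomial_drift) {
  const int K = p0.size();
  NumericMatrix out(generations + 1, K);
  std::vector<double> p(p0.begin(), p0.end());
  for (int k = 0; k < K; ++k) out(0, k) = p[k];

  std::vector<double> G((size_t) K * K);
  std::vector<double> pp(K);
  std::vector<int> xm(K);
  const double n = pop_size;

  // homing conversion in drive heterozygotes: Binomial(n, c_j * H_j) / n,
  // clamped to the available heterozygote mass
  auto convert = [&]() {
    for (int j = 1; j < K; ++j) {
      double cj = susc[j];
      double h = 2.0 * G[(size_t) j * K]; // G[0, j]
      if (cj > 0.0 && h > 0.0) {
        double prob = cj * h;
        double dH = stochastic ? R::rbinom(n, prob) / n : prob;
        if (dH > h) dH = h;
        double half = dH / 2.0;
        G[(size_t) j * K] -= half;
        G[j] -= half;
        G[0] += dH;
      }
    }
  };

  // mass removed from a drive-carrying genotype of frequency g with
  // effective dominance weight d_eff
  auto sel_removed = [&](double g, double d_eff) -> double {
    if (stochastic) {
      double trials = Rf_fround(exposure * g * n, 0.0);
      double prob = d_eff * fitness_cost;
      if (trials >= 1.0 && prob > 0.0) return R::rbinom(trials, prob) / n;
      return 0.0;
    }
    return exposure * g * d_eff * fitness_cost;
  };

  auto select = [&]() {
    double g = G[0]; // drive homozygote, d_eff = 1
    double rem = sel_removed(g, 1.0);
    if (rem > g) rem = g;
    G[0] = g - rem;
    for (int j = 1; j < K; ++j) {
      double h = 2.0 * G[(size_t) j * K];
      if (h > 0.0) {
        double remh = sel_removed(h, dominance);
        if (remh > h) remh = h;
        double half = remh / 2.0;
        G[(size_t) j * K] -= half;
        G[j] -= half;
      }
    }
    double tot = sum_ld(G);
    for (size_t m = 0; m < G.size(); ++m) G[m] /= tot;
  };

  int t = 1;
  for (; t <= generations; ++t) {
    // zygote formation with inbreeding excess homozygosity
    for (int j = 0; j < K; ++j)
      for (int i = 0; i < K; ++i)
        G[(size_t) i + (size_t) j * K] =
          (i == j) ? p[i] * p[i] + inbreeding * p[i] * (1.0 - p[i])
                   : (1.0 - inbreeding) * (p[i] * p[j]);

    if (postzygotic) convert();
    select();
    if (!postzygotic) convert();

    // collapse genotypes back to allele frequencies (row sums)
    for (int i = 0; i < K; ++i) {
      long double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += G[(size_t) i + (size_t) j * K];
      p[i] = (double) acc;
    }

    // Wright-Fisher drift on the gamete pool
    if (stochastic) {
      if (multinomial_drift) {
        double *pr = p.data();
        rmultinom((int) (2.0 * n), pr, K, xm.data());
        for (int i = 0; i < K; ++i) pp[i] = xm[i] / (2.0 * n);
      } else {
        for (int i = 0; i < K; ++i) {
          double x = (p[i] > 0.0 && p[i] < 1.0) ? R::rbinom(2.0 * n, p[i])
                                                : p[i] * (2.0 * n);
          pp[i] = x / (2.0 * n);
        }
      }
      long double acc = 0.0;
      for (int i = 0; i < K; ++i) acc += pp[i];
      double tot = (double) acc;
      if (tot > 0.0)
        for (int i = 0; i < K; ++i) p[i] = pp[i] / tot;
    }

    for (int k = 0; k < K; ++k) out(t, k) = p[k];

    // absorbing boundaries: no mutation can re-create a lost drive, and a
    // fixed drive cannot be displaced; freeze the remaining trajectory
    if (p[0] == 0.0 || p[0] == 1.0) {
      for (int t2 = t + 1; t2 <= generations; ++t2)
        for (int k = 0; k < K; ++k) out(t2, k) = p[k];
      break;
    }
  }
  return out;
}
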