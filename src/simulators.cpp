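#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Ricker model: y_t ~ Pois(phi * N_t), N_{t+1} = r * N_t * exp(-N_t + e_t),
// e_t ~ N(0, sigma^2). Hidden state starts at n0 and a burn-in stretch is
// discarded before observations are emitted. Uses R's RNG stream so that
// set.seed() governs reproducibility end to end.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector ricker_sim_cpp(double r, double sigma, double phi, int T,
                             int burnin, double n0) {
  if (T < 1) stop("T must be >= 1");
  IntegerVector y(T);
  double N = n0;
  for (int t = -burnin; t < T; ++t) {
    if (!std::isfinite(N))
      stop("non-finite Ricker trajectory at r=%g, sigma=%g, phi=%g",
           r, sigma, phi);
    if (t >= 0) y[t] = (int) R::rpois(phi * N);
    double e = sigma > 0 ? R::rnorm(0.0, sigma) : 0.0;
    N = r * N * std::exp(-N + e);
  }
  return y;
}

// Summary vector of a count series: mean, proportion of zeros,
// autocovariances at lags 1..5 (biased, denominator T), and the three OLS
// coefficients of x_t = y_t^0.3 regressed on {1, x_{t-1}, x_{t-1}^2}.
// A degenerate (constant-x) design yields coefficients (mean(x), 0, 0).
static void ricker_stats_core(const int *y, int n, double *out) {
  double m = 0.0;
  int nz = 0;
  for (int i = 0; i < n; ++i) {
    m += y[i];
    if (y[i] == 0) ++nz;
  }
  m /= n;
  out[0] = m;
  out[1] = (double) nz / n;
  for (int k = 1; k <= 5; ++k) {
    double s = 0.0;
    for (int i = 0; i + k < n; ++i) s += (y[i] - m) * (y[i + k] - m);
    out[1 + k] = s / n;
  }
  // quadratic autoregression of x = y^0.3 on its own lag
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = std::pow((double) y[i], 0.3);
  // normal equations for design [1, z, z^2], z = lagged x
  double S[3][3] = {{0}}, b[3] = {0};
  for (int i = 1; i < n; ++i) {
    double z = x[i - 1], z2 = z * z, t = x[i];
    S[0][0] += 1;  S[0][1] += z;      S[0][2] += z2;
    S[1][1] += z2; S[1][2] += z * z2; S[2][2] += z2 * z2;
    b[0] += t; b[1] += t * z; b[2] += t * z2;
  }
  S[1][0] = S[0][1]; S[2][0] = S[0][2]; S[2][1] = S[1][2];
  // Gaussian elimination with partial pivoting; singular -> (mean(x), 0, 0)
  double A[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) A[i][j] = S[i][j];
    A[i][3] = b[i];
  }
  bool singular = false;
  for (int c = 0; c < 3 && !singular; ++c) {
    int p = c;
    for (int rr = c + 1; rr < 3; ++rr)
      if (std::fabs(A[rr][c]) > std::fabs(A[p][c])) p = rr;
    if (std::fabs(A[p][c]) < 1e-10 * (S[0][0] + S[1][1] + S[2][2] + 1e-300)) {
      singular = true;
      break;
    }
    if (p != c)
      for (int j = c; j < 4; ++j) std::swap(A[p][j], A[c][j]);
    for (int rr = c + 1; rr < 3; ++rr) {
      double f = A[rr][c] / A[c][c];
      for (int j = c; j < 4; ++j) A[rr][j] -= f * A[c][j];
    }
  }
  if (singular) {
    double mx = 0.0;
    for (int i = 1; i < n; ++i) mx += x[i];
    out[7] = mx / (n - 1);
    out[8] = 0.0;
    out[9] = 0.0;
  } else {
    double beta[3];
    for (int c = 2; c >= 0; --c) {
      double s = A[c][3];
      for (int j = c + 1; j < 3; ++j) s -= A[c][j] * beta[j];
      beta[c] = s / A[c][c];
    }
    out[7] = beta[0]; out[8] = beta[1]; out[9] = beta[2];
  }
}

// [[Rcpp::export]]
NumericVector ricker_summary_cpp(IntegerVector y) {
  if (y.size() < 7) stop("series too short: need length >= 7");
  NumericVector out(10);
  ricker_stats_core(&y[0], y.size(), &out[0]);
  return out;
}

// Summaries of contiguous non-overlapping splits of length tlen; the
// leftover tail is discarded.
// [[Rcpp::export]]
NumericMatrix ricker_split_summaries_cpp(IntegerVector y, int tlen,
                                         int max_splits) {
  int ns = y.size() / tlen;
  if (max_splits > 0 && ns > max_splits) ns = max_splits;
  NumericMatrix out(ns, 10);
  std::vector<double> buf(10);
  for (int s = 0; s < ns; ++s) {
    ricker_stats_core(&y[(R_xlen_t) s * tlen], tlen, buf.data());
    for (int j = 0; j < 10; ++j) out(s, j) = buf[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trait-based community model. A local community of J individuals drawn from
// a regional pool of S species evenly spaced on the trait axis [0, 100].
// Each step one uniformly chosen local individual dies; with probability
// I/(I+J+1) it is replaced by an immigrant species (uniform over the pool),
// otherwise by the offspring of a local individual chosen with probability
// proportional to its competitiveness F(u) = 1 + A exp(-(u-h)^2/(2 sf^2)).
// Parent sampling uses rejection against Fmax = 1 + A, so a death is O(1).
// ---------------------------------------------------------------------------

struct TraitSim {
  int S, J;
  std::vector<double> F;      // competitiveness per species
  std::vector<int> species;   // species index per local individual
  std::vector<int> counts;    // abundance per species
  double Fmax, pimm;

  TraitSim(double I, double A, double h, double sf, int S_, int J_)
      : S(S_), J(J_), F(S_), species(J_), counts(S_, 0) {
    double du = S > 1 ? 100.0 / (S - 1) : 0.0;
    for (int s = 0; s < S; ++s) {
      double u = s * du;
      F[s] = 1.0 + A * std::exp(-(u - h) * (u - h) / (2.0 * sf * sf));
    }
    Fmax = 1.0 + A;
    pimm = I / (I + J + 1.0);
    for (int i = 0; i < J; ++i) {
      int s = (int) (unif_rand() * S);
      if (s == S) s = S - 1;
      species[i] = s;
      counts[s]++;
    }
  }

  void step() {
    int dead = (int) (unif_rand() * J);
    if (dead == J) dead = J - 1;
    int newsp;
    if (unif_rand() < pimm) {
      newsp = (int) (unif_rand() * S);
      if (newsp == S) newsp = S - 1;
    } else {
      // rejection-sample a local parent (excluding the dead individual)
      for (;;) {
        int p = (int) (unif_rand() * J);
        if (p == J || p == dead) continue;
        if (unif_rand() * Fmax <= F[species[p]]) {
          newsp = species[p];
          break;
        }
      }
    }
    counts[species[dead]]--;
    counts[newsp]++;
    species[dead] = newsp;
  }

  // richness, Shannon entropy, mean trait, trait skewness of the community
  void stats(double *out) const {
    double du = S > 1 ? 100.0 / (S - 1) : 0.0;
    int rich = 0;
    double H = 0.0, m1 = 0.0;
    for (int s = 0; s < S; ++s) {
      if (counts[s] > 0) {
        ++rich;
        double p = (double) counts[s] / J;
        H -= p * std::log(p);
        m1 += p * s * du;
      }
    }
    double v = 0.0, m3 = 0.0;
    for (int s = 0; s < S; ++s) {
      if (counts[s] > 0) {
        double p = (double) counts[s] / J, d = s * du - m1;
        v += p * d * d;
        m3 += p * d * d * d;
      }
    }
    out[0] = rich;
    out[1] = H;
    out[2] = m1;
    out[3] = v > 0 ? m3 / std::pow(v, 1.5) : 0.0;
  }
};

// Snapshot statistics: one row per snapshot, recorded every `thinning`
// deaths after `burnin` discarded deaths.
// [[Rcpp::export]]
NumericMatrix trait_sim_stats_cpp(double I, double A, double h, double sf,
                                  int S, int J, int thinning, int n_snapshots,
                                  int burnin) {
  TraitSim sim(I, A, h, sf, S, J);
  for (int i = 0; i < burnin; ++i) sim.step();
  NumericMatrix out(n_snapshots, 4);
  double buf[4];
  for (int k = 0; k < n_snapshots; ++k) {
    for (int i = 0; i < thinning; ++i) sim.step();
    sim.stats(buf);
    for (int j = 0; j < 4; ++j) out(k, j) = buf[j];
  }
  return out;
}

// Raw abundance snapshots (rows: snapshots, cols: regional species).
// [[Rcpp::export]]
IntegerMatrix trait_sim_states_cpp(double I, double A, double h, double sf,
                                   int S, int J, int thinning,
                                   int n_snapshots, int burnin) {
  TraitSim sim(I, A, h, sf, S, J);
  for (int i = 0; i < burnin; ++i) sim.step();
  IntegerMatrix out(n_snapshots, S);
  for (int k = 0; k < n_snapshots; ++k) {
    for (int i = 0; i < thinning; ++i) sim.step();
    for (int s = 0; s < S; ++s) out(k, s) = sim.counts[s];
  }
  return out;
}
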