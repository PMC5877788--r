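// Core numerical routines: Gittins index computation for Bernoulli arms with
// Beta posterior states, and the Monte-Carlo forward-looking rollout that
// turns Gittins indices into block allocation probabilities (FLGI), including
// the resampling loop of the randomisation test.  All randomness here uses a
// self-contained counter-based generator so that per-state rollout results
// are reproducible regardless of call order (required for state caching).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream.  Statistically adequate for Monte-Carlo sampling
// of categorical/Bernoulli draws; chosen for seedability from a hash.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {
    // warm up so nearby seeds decorrelate
    splitmix64_next(state);
    splitmix64_next(state);
  }
  double unif() {
    return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  int sample_int(int n) {  // uniform on 0..n-1
    return (int)(unif() * n) % n;
  }
};

static inline uint64_t mix_seed(uint64_t a, uint64_t b) {
  uint64_t x = a ^ (0x9E3779B97F4A7C15ULL + (b << 6) + (b >> 2));
  splitmix64_next(x);
  return x ^ b;
}

// ---------------------------------------------------------------------------
// Gittins indices.
//
// The index nu(s, f) of a Bernoulli arm with Beta(s, f) posterior and
// discount d is the retirement rate lambda at which continuing the arm and
// retiring on a known arm of rate lambda have equal value.  Values are
// computed by backward induction over the triangular lattice of reachable
// posterior states, truncated at `horizon` pulls (terminal value 0; both the
// continue and the retire branch lose the same discounted tail, so the
// truncation error on the index is of order d^horizon).
// ---------------------------------------------------------------------------

// Single-state index via bisection on lambda.
// [[Rcpp::export]]
double cpp_gittins_index(double s0, double f0, double d, int horizon,
                         double tol) {
  if (s0 <= 0.0 || f0 <= 0.0)
    stop("pseudo-counts must be positive");
  if (d < 0.0 || d >= 1.0)
    stop("discount must lie in [0, 1)");
  if (horizon < 1)
    stop("horizon must be >= 1");

  // geo[n] = (1 - d^n) / (1 - d): value of receiving 1 per step for n steps
  std::vector<double> geo(horizon + 1);
  geo[0] = 0.0;
  double dn = 1.0;
  for (int n = 1; n <= horizon; ++n) {
    geo[n] = geo[n - 1] + dn;
    dn *= d;
  }

  std::vector<double> vnext(horizon + 2), vcur(horizon + 2);
  double lo = 0.0, hi = 1.0;
  while (hi - lo > tol) {
    double lam = 0.5 * (lo + hi);
    // terminal layer m = horizon: no steps remain
    for (int i = 0; i <= horizon; ++i) vnext[i] = 0.0;
    double cont_root = 0.0;
    for (int m = horizon - 1; m >= 0; --m) {
      int nrem = horizon - m;           // steps remaining below this layer
      double retire = lam * geo[nrem];
      double tot = s0 + f0 + m;
      for (int i = 0; i <= m; ++i) {    // i = successes accrued since root
        double p = (s0 + i) / tot;
        double cont = p * (1.0 + d * vnext[i + 1]) + (1.0 - p) * d * vnext[i];
        vcur[i] = cont > retire ? cont : retire;
      }
      if (m == 0) {
        double p = s0 / (s0 + f0);
        cont_root = p * (1.0 + d * vnext[1]) + (1.0 - p) * d * vnext[0];
      }
      std::swap(vcur, vnext);
    }
    if (horizon == 1) {
      cont_root = s0 / (s0 + f0);
    }
    if (cont_root >= lam * geo[horizon]) lo = lam; else hi = lam;
  }
  return 0.5 * (lo + hi);
}

// Whole-table computation.  One backward induction per lambda value yields
// the continue/retire decision at *every* lattice state simultaneously, so
// the full table costs (1/grid) inductions instead of one bisection per
// state.  The crossing lambda is bracketed to width `step` = 2 * tol and the
// midpoint reported, giving |error| <= tol (+ O(d^horizon) truncation).
// Returned matrix: entry [s, f] (1-based pseudo-counts as row/col indices)
// for s, f >= 1 and s + f <= smax; NA elsewhere.
// [[Rcpp::export]]
NumericMatrix cpp_build_gi_table(int smax, double d, int horizon, double tol) {
  if (smax < 2) stop("smax must be >= 2");
  if (d < 0.0 || d >= 1.0) stop("discount must lie in [0, 1)");
  if (horizon < 1) stop("horizon must be >= 1");
  if (tol <= 0.0 || tol >= 0.5) stop("tol must lie in (0, 0.5)");

  const int dmax = smax + horizon;      // deepest lattice layer (s + f = dmax)
  const double step = 2.0 * tol;
  const int ngrid = (int)std::ceil(1.0 / step);

  std::vector<double> geo(dmax + 1);
  {
    geo[0] = 0.0;
    double dn = 1.0;
    for (int n = 1; n <= dmax; ++n) { geo[n] = geo[n - 1] + dn; dn *= d; }
  }

  // cross[s * (smax + 1) + f] = largest grid lambda at which continuing is
  // still (weakly) preferred; -1 marks "never" (cannot occur for lambda = 0).
  std::vector<double> cross((size_t)(smax + 1) * (smax + 1), -1.0);
  std::vector<double> vnext(dmax + 2), vcur(dmax + 2);

  for (int g = 0; g <= ngrid; ++g) {
    double lam = g * step;
    if (lam > 1.0) lam = 1.0;
    // terminal layer D = dmax + 1 treated as all-zero future
    for (int i = 0; i <= dmax + 1; ++i) vnext[i] = 0.0;
    for (int D = dmax; D >= 2; --D) {   // D = s + f of the layer
      int nrem = dmax - D + 1;          // pulls remaining below layer D
      double retire = lam * geo[nrem];
      bool record = D <= smax;
      for (int s = 1; s <= D - 1; ++s) {
        double p = (double)s / D;
        double cont = p * (1.0 + d * vnext[s + 1]) + (1.0 - p) * d * vnext[s];
        vcur[s] = cont > retire ? cont : retire;
        if (record && cont >= retire)
          cross[(size_t)s * (smax + 1) + (D - s)] = lam;
      }
      vcur[0] = 0.0;
      vcur[D] = 0.0;
      std::swap(vcur, vnext);
    }
  }

  NumericMatrix out(smax + 1, smax + 1);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int s = 1; s <= smax - 1; ++s) {
    for (int f = 1; f <= smax - s; ++f) {
      double c = cross[(size_t)s * (smax + 1) + f];
      double nu = (c < 0.0) ? 0.5 * step : c + 0.5 * step;
      if (nu > 1.0) nu = 1.0;
      out(s, f) = nu;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// FLGI rollout.
//
// Given current posterior pseudo-counts per arm, the probability that a
// patient in the upcoming block of size b is allocated to arm k is estimated
// by Monte Carlo: replay the block `nreps` times, each time allocating the b
// virtual patients greedily by Gittins index (ties uniform at random) and
// drawing virtual outcomes from the posterior predictive mean, then average
// the allocated fractions.
// ---------------------------------------------------------------------------

struct FlgiCache {
  std::unordered_map<uint64_t, std::vector<double>> map;
};

// [[Rcpp::export]]
SEXP cpp_flgi_cache_new() {
  XPtr<FlgiCache> p(new FlgiCache(), true);
  return p;
}

// [[Rcpp::export]]
int cpp_flgi_cache_size(SEXP cache) {
  XPtr<FlgiCache> p(cache);
  return (int)p->map.size();
}

static inline uint64_t pack_state(const int *s, const int *f, int narms) {
  // 10 bits per pseudo-count (< 1024), plus arm count in the top bits
  uint64_t key = (uint64_t)narms;
  for (int k = 0; k < narms; ++k) {
    key = (key << 10) | (uint64_t)(s[k] & 1023);
    key = (key << 10) | (uint64_t)(f[k] & 1023);
  }
  return key;
}

static std::vector<double> flgi_rollout(const int *s0, const int *f0,
                                        int narms, int b, int nreps,
                                        const NumericMatrix &gi,
                                        uint64_t seed) {
  const int smax = gi.nrow() - 1;
  std::vector<double> alloc(narms, 0.0);
  std::vector<int> s(narms), f(narms), best(narms);
  Rng rng(seed);
  for (int r = 0; r < nreps; ++r) {
    for (int k = 0; k < narms; ++k) { s[k] = s0[k]; f[k] = f0[k]; }
    for (int i = 0; i < b; ++i) {
      int nbest = 0;
      double vbest = -1.0;
      for (int k = 0; k < narms; ++k) {
        if (s[k] + f[k] > smax)
          stop("Gittins table too shallow for the requested trial");
        double v = gi(s[k], f[k]);
        if (ISNA(v))
          stop("Gittins table too shallow for the requested trial");
        if (v > vbest) { vbest = v; best[0] = k; nbest = 1; }
        else if (v == vbest) { best[nbest++] = k; }
      }
      int a = (nbest == 1) ? best[0] : best[rng.sample_int(nbest)];
      alloc[a] += 1.0;
      double p = (double)s[a] / (s[a] + f[a]);
      if (rng.unif() < p) s[a] += 1; else f[a] += 1;
    }
  }
  double tot = (double)nreps * b;
  for (int k = 0; k < narms; ++k) alloc[k] /= tot;
  return alloc;
}

static std::vector<double> flgi_probs_cached(const int *s, const int *f,
                                             int narms, int b, int nreps,
                                             const NumericMatrix &gi,
                                             uint64_t base_seed,
                                             FlgiCache *cache) {
  // exact symmetry: identical arm states share the block uniformly
  bool sym = true;
  for (int k = 1; k < narms; ++k)
    if (s[k] != s[0] || f[k] != f[0]) { sym = false; break; }
  if (sym) return std::vector<double>(narms, 1.0 / narms);

  uint64_t key = pack_state(s, f, narms);
  if (cache != nullptr) {
    auto it = cache->map.find(key);
    if (it != cache->map.end()) return it->second;
  }
  std::vector<double> probs =
      flgi_rollout(s, f, narms, b, nreps, gi, mix_seed(base_seed, key));
  if (cache != nullptr) cache->map.emplace(key, probs);
  return probs;
}

// [[Rcpp::export]]
NumericVector cpp_flgi_probs(IntegerVector s, IntegerVector f, int b,
                             int nreps, NumericMatrix gi, double base_seed,
                             SEXP cache) {
  int narms = s.size();
  if (f.size() != narms) stop("length mismatch between s and f");
  if (b < 1 || nreps < 1) stop("b and nreps must be >= 1");
  FlgiCache *cp = nullptr;
  if (!Rf_isNull(cache)) { XPtr<FlgiCache> p(cache); cp = p.get(); }
  std::vector<double> probs = flgi_probs_cached(
      INTEGER(s), INTEGER(f), narms, b, nreps, gi, (uint64_t)base_seed, cp);
  return NumericVector(probs.begin(), probs.end());
}

// ---------------------------------------------------------------------------
// Randomisation-test resampling for a 2-arm FLGI trial.
//
// Outcomes y (b x J, by patient position) are pinned; M re-randomised trials
// are generated by re-running the FLGI rule block by block, with block-1
// allocation uniform and later blocks using the rollout probabilities
// computed from the re-randomised earlier blocks and the pinned outcomes.
// Returns the difference in success proportions (arm 1 minus arm 0) per
// resample; an empty arm yields statistic 0 and is counted as degenerate.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_flgi_rand_test(IntegerMatrix y, int prior_a, int prior_b,
                        int nreps, NumericMatrix gi, int M,
                        double base_seed, SEXP cache) {
  const int b = y.nrow(), J = y.ncol();
  const int narms = 2;
  FlgiCache *cp = nullptr;
  if (!Rf_isNull(cache)) { XPtr<FlgiCache> p(cache); cp = p.get(); }

  NumericVector stats(M);
  int ndegen = 0;
  int s[2], f[2], n[2], x[2];
  for (int m = 0; m < M; ++m) {
    Rng rng(mix_seed((uint64_t)base_seed, 0x52414E44ULL + (uint64_t)m));
    s[0] = s[1] = prior_a;
    f[0] = f[1] = prior_b;
    n[0] = n[1] = x[0] = x[1] = 0;
    for (int j = 0; j < J; ++j) {
      double p1;
      if (j == 0) {
        p1 = 0.5;
      } else {
        std::vector<double> probs = flgi_probs_cached(
            s, f, narms, b, nreps, gi, (uint64_t)base_seed, cp);
        p1 = probs[1];
      }
      for (int i = 0; i < b; ++i) {
        int a = (rng.unif() < p1) ? 1 : 0;
        int yv = y(i, j);
        n[a] += 1;
        x[a] += yv;
        if (yv == 1) s[a] += 1; else f[a] += 1;
      }
    }
    if (n[0] == 0 || n[1] == 0) {
      stats[m] = 0.0;
      ++ndegen;
    } else {
      stats[m] = (double)x[1] / n[1] - (double)x[0] / n[0];
    }
  }
  return List::create(_["stats"] = stats, _["n_degenerate"] = ndegen);
}
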