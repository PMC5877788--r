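# Shared fixtures and independent oracles for the test suite.
# Gittins tables are memoised per session via gi_table_default(), so deep
# tables are built once and shared across test files.

# small, fast Gittins table (short horizon through the low discount)
gi_small <- function() gi_table_default(15, discount = 0.9, tol = 1e-4)

# Exhaustive enumeration of the greedy-Gittins block rollout: the exact
# expected fraction of a block of size b allocated to each arm, with ties
# broken uniformly and virtual outcomes from the posterior predictive mean.
# Independent of the C++ rollout (pure R recursion over all outcome paths).
flgi_exact <- function(s, f, b, table) {
  narms <- length(s)
  rec <- function(s, f, left) {
    if (left == 0) return(rep(0, narms))
    g <- gi_lookup(table, s, f)
    amax <- which(abs(g - max(g)) < 1e-15)
    out <- rep(0, narms)
    for (a in amax) {
      p <- s[a] / (s[a] + f[a])
      sw <- s; sw[a] <- sw[a] + 1
      fw <- f; fw[a] <- fw[a] + 1
      contrib <- rep(0, narms)
      contrib[a] <- 1 / b
      contrib <- contrib + p * rec(sw, f, left - 1) +
        (1 - p) * rec(s, fw, left - 1)
      out <- out + contrib / length(amax)
    }
    out
  }
  rec(s, f, b)
}

# random posterior-count states for property sweeps
random_counts <- function(narms, max_n = 30) {
  n <- sample.int(max_n, narms, replace = TRUE)
  x <- rbinom(narms, n, runif(narms))
  structure(list(s = 1 + x, f = 1 + n - x, n = n),
            class = "posterior_counts")
}

# tiny complete-randomisation design for fast end-to-end runs
tiny_design <- function(K = 1, b = 6, J = 4)
  design_spec(K = K, T_total = b * J, J = J, b = b)
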