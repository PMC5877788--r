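#' Allocation-rule configuration
#'
#' Tuning knobs shared by the block-wise allocation rules:
#' * `ts_mc_draws` — posterior draws for the Thompson-sampling probability
#'   of being the best arm.
#' * `flgi_mc_reps` — Monte-Carlo rollout replicates per block for the
#'   forward-looking Gittins index (FLGI) probabilities.
#' * `gamma` — the doubly-adaptive biased coin (DBCD) exponent; larger
#'   values push the realised allocation harder toward the target.
#' * `rsihr_form` — `"sqrt"` uses the Rosenberger optimal 2-arm target
#'   `sqrt(p1) / (sqrt(p0) + sqrt(p1))`; `"ratio"` the plain
#'   `p1 / (p0 + p1)` variant.
#' * `rsihr_floor` — lower bound per arm in the multi-arm numerical target.
#'
#' @param rule one of `"CR"`, `"TS"`, `"RSIHR"`, `"FLGI"`, `"CFLGI"`.
#' @param ts_mc_draws,flgi_mc_reps,gamma,rsihr_form,rsihr_floor see above.
#' @return a `policy_config` list.
#' @export
policy_config <- function(rule = c("CR", "TS", "RSIHR", "FLGI", "CFLGI"),
                          ts_mc_draws = 1e4, flgi_mc_reps = 100,
                          gamma = 2, rsihr_form = c("sqrt", "ratio"),
                          rsihr_floor = 0.05) {
  rule <- match.arg(rule)
  rsihr_form <- match.arg(rsihr_form)
  if (gamma < 0) stop_domain("gamma must be >= 0")
  if (ts_mc_draws < 1 || flgi_mc_reps < 1)
    stop_domain("Monte-Carlo counts must be >= 1")
  structure(list(rule = rule, ts_mc_draws = as.integer(ts_mc_draws),
                 flgi_mc_reps = as.integer(flgi_mc_reps), gamma = gamma,
                 rsihr_form = rsihr_form, rsihr_floor = rsihr_floor),
            class = "policy_config")
}

#' Complete-randomisation probabilities
#'
#' The fixed equal allocation `1 / (K + 1)` for every block, independent of
#' the accumulated data.
#'
#' @param j block index (unused; kept for the common policy signature).
#' @param counts a [posterior_counts()] object (unused).
#' @return allocation probabilities over arms `0..K`.
#' @export
cr_policy <- function(j, counts) {
  rep(1 / length(counts$s), length(counts$s))
}

#' Posterior probability of being the best arm
#'
#' Monte-Carlo estimate, per arm, of the posterior probability that its
#' success rate is the strictly largest, from independent Beta posterior
#' draws; ties (zero-probability events) are broken uniformly at random.
#'
#' @param counts a [posterior_counts()] object.
#' @param mc_draws number of joint posterior draws.
#' @return a probability vector over arms `0..K` summing to 1.
#' @export
prob_best <- function(counts, mc_draws = 1e4) {
  narms <- length(counts$s)
  draws <- matrix(rbeta(mc_draws * narms, rep(counts$s, each = mc_draws),
                        rep(counts$f, each = mc_draws)), mc_draws, narms)
  best <- max.col(draws, ties.method = "random")
  tabulate(best, narms) / mc_draws
}

#' Tuned Thompson-sampling probabilities
#'
#' Thompson sampling allocates proportionally to the posterior probability
#' of being the best arm, raised to the tuning exponent
#' `c = (j - 1) b / (2 T)`: the rule starts uniform (`c = 0` at block 1)
#' and grows more aggressive as data accumulate.
#'
#' @param j block index.
#' @param counts a [posterior_counts()] object.
#' @param design a [design_spec()].
#' @param config a [policy_config()].
#' @return allocation probabilities over arms `0..K`.
#' @export
ts_probabilities <- function(j, counts, design, config = policy_config("TS")) {
  if (j < 1 || j > design$J) stop_domain("block index j must lie in 1..J")
  cexp <- (j - 1) * design$b / (2 * design$T_total)
  ts_alloc_weights(prob_best(counts, config$ts_mc_draws), cexp)
}

# allocation weights pb^c, simplex-normalised; uniform fallback if all
# weights underflow
ts_alloc_weights <- function(pb, cexp) {
  w <- pb^cexp
  if (!any(w > 0)) {
    warning("all tuned Thompson weights vanished; falling back to uniform")
    return(rep(1 / length(w), length(w)))
  }
  w / sum(w)
}

#' Failure-minimising target allocation (RSIHR)
#'
#' For a 2-arm trial the Rosenberger optimal allocation, minimising the
#' expected number of failures at fixed variance of the treatment-effect
#' estimator, assigns the experimental arm
#' \eqn{\rho_1 = \sqrt{p_1} / (\sqrt{p_0} + \sqrt{p_1})}.  For `K > 1` no
#' closed form exists; the target is found numerically by minimising the
#' expected failures subject to the control-vs-best-arm Wald variance not
#' exceeding its value under equal allocation, on the simplex with a lower
#' floor per arm.
#'
#' @param p_hat estimated success rates per arm `0..K` (clamped into
#'   `[0.01, 0.99]` with a warning if outside `(0, 1)`).
#' @param config a [policy_config()] (target form, floor).
#' @return the target allocation vector `rho` over arms `0..K`.
#' @examples
#' rsihr_target(c(0.1, 0.9))  # rho_1 = 0.75
#' @export
rsihr_target <- function(p_hat, config = policy_config("RSIHR")) {
  if (any(p_hat <= 0 | p_hat >= 1)) {
    warning("success-rate estimates clamped into [0.01, 0.99]")
    p_hat <- pmin(pmax(p_hat, 0.01), 0.99)
  }
  K <- length(p_hat) - 1
  if (K == 1) {
    w <- if (config$rsihr_form == "sqrt") sqrt(p_hat) else p_hat
    rho1 <- w[2] / (w[1] + w[2])
    return(c(1 - rho1, rho1))
  }
  rsihr_target_multiarm(p_hat, config$rsihr_floor)
}

# Multi-arm failure minimisation: minimise sum_k rho_k (1 - p_k) subject to
# var(p0_hat - pbest_hat) <= its value at equal allocation, rho on the
# simplex with a floor.  Solved by penalised Nelder-Mead on softmax
# coordinates (smooth, K + 1 <= a handful of arms).
rsihr_target_multiarm <- function(p_hat, floor) {
  narms <- length(p_hat)
  kbest <- which.max(p_hat[-1]) + 1L
  vfun <- function(rho) p_hat[1] * (1 - p_hat[1]) / rho[1] +
    p_hat[kbest] * (1 - p_hat[kbest]) / rho[kbest]
  vmax <- vfun(rep(1 / narms, narms))
  obj <- function(theta) {
    rho <- exp(theta) / sum(exp(theta))
    rho <- floor + (1 - narms * floor) * rho  # keep the floor smoothly
    sum(rho * (1 - p_hat)) + 1e3 * max(0, vfun(rho) - vmax)^2
  }
  fit <- optim(rep(0, narms), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  rho <- exp(fit$par) / sum(exp(fit$par))
  floor + (1 - narms * floor) * rho
}

#' Doubly-adaptive biased coin probabilities
#'
#' Hu and Zhang's allocation function pushes the realised allocation
#' proportions `x_k = n_k / sum(n)` toward the target `rho` from
#' [rsihr_target()]:
#' \deqn{\pi_k \propto \rho_k (\rho_k / x_k)^\gamma.}
#' Success rates are estimated by the prior mean before any data (block 1)
#' and by the posterior mean thereafter.  If any `x_k = 0` the target is
#' returned directly.
#'
#' @inheritParams ts_probabilities
#' @param p_hat optional success-rate estimates; defaults to the posterior
#'   means from `counts`.
#' @return allocation probabilities over arms `0..K`.
#' @export
dbcd_probabilities <- function(j, counts, design,
                               config = policy_config("RSIHR"),
                               p_hat = NULL) {
  p_hat <- p_hat %||% (counts$s / (counts$s + counts$f))
  rho <- rsihr_target(p_hat, config)
  ntot <- sum(counts$n)
  if (ntot == 0 || any(counts$n == 0)) return(rho)
  x <- counts$n / ntot
  w <- rho * (rho / x)^config$gamma
  w / sum(w)
}

#' Forward-looking Gittins index probabilities
#'
#' Estimates the probability that a patient in the upcoming block of size
#' `b` is allocated to each arm under greedy Gittins-index play: the block
#' is replayed `flgi_mc_reps` times, each time allocating the `b` virtual
#' patients to the arm with the currently largest tabulated index (ties
#' uniform at random) and drawing virtual outcomes from the arm's posterior
#' predictive mean; the averaged allocation fractions are the block
#' probabilities.  When all arms are in identical posterior states the
#' exact symmetric answer (uniform) is returned.
#'
#' @inheritParams ts_probabilities
#' @param gi_table a [build_gi_table()] covering every state reachable
#'   within the trial.
#' @param seed integer seed for the rollout stream; each posterior state
#'   gets a deterministic sub-stream so results do not depend on call order.
#' @param cache optional cache handle from `cpp_flgi_cache_new()`; states
#'   recur constantly within a trial and across randomisation-test
#'   resamples, so caching is essential at simulation scale.
#' @return allocation probabilities over arms `0..K`.
#' @export
flgi_probabilities <- function(j, counts, design,
                               config = policy_config("FLGI"),
                               gi_table, seed = 1L, cache = NULL) {
  stopifnot(inherits(gi_table, "gi_table"))
  s <- as.integer(round(counts$s))
  f <- as.integer(round(counts$f))
  if (any(abs(s - counts$s) > 1e-9) || any(abs(f - counts$f) > 1e-9))
    stop_domain("FLGI requires integer pseudo-counts (integer Beta prior)")
  cpp_flgi_probs(s, f, design$b, config$flgi_mc_reps, gi_table$values,
                 as.numeric(seed), cache)
}

#' Control-protected FLGI probabilities
#'
#' The controlled FLGI fixes the control-arm allocation at exactly
#' `1 / (K + 1)` (its equal-randomisation share) and distributes the
#' remaining `K / (K + 1)` mass over the experimental arms proportionally
#' to the FLGI probabilities computed among the experimental arms alone.
#'
#' @inheritParams flgi_probabilities
#' @return allocation probabilities over arms `0..K`; element 1 (control)
#'   always equals `1 / (K + 1)`.
#' @export
cflgi_probabilities <- function(j, counts, design,
                                config = policy_config("CFLGI"),
                                gi_table, seed = 1L, cache = NULL) {
  narms <- length(counts$s)
  if (narms < 2) stop_domain("CFLGI needs at least one experimental arm")
  sub <- list(s = counts$s[-1], f = counts$f[-1], n = counts$n[-1])
  class(sub) <- "posterior_counts"
  pexp <- flgi_probabilities(j, sub, design, config, gi_table, seed, cache)
  c(1 / narms, (1 - 1 / narms) * pexp)
}

#' Build an allocation policy
#'
#' Wires a rule and its configuration to a design, returning a policy
#' object whose `$probs(j, counts)` closure maps the accumulated data
#' (blocks `1..j-1`) to the block-`j` allocation probabilities.  FLGI-type
#' policies own a rollout cache and a fixed rollout seed, so repeated calls
#' on the same posterior state return identical probabilities.
#'
#' @param rule rule name or a [policy_config()].
#' @param design a [design_spec()].
#' @param gi_table Gittins table for FLGI/CFLGI; defaults to a memoised
#'   table of depth `T_total` at discount 0.995.
#' @param seed rollout seed for FLGI-type rules.
#' @param ... passed to [policy_config()] when `rule` is a name.
#' @return an object of class `rar_policy`.
#' @examples
#' d <- design_spec(K = 1, T_total = 20, J = 4, b = 5)
#' pol <- make_policy("CR", d)
#' pol$probs(2, posterior_counts(d))
#' @export
make_policy <- function(rule, design, gi_table = NULL, seed = 1L, ...) {
  config <- if (inherits(rule, "policy_config")) rule
            else policy_config(rule, ...)
  needs_gi <- config$rule %in% c("FLGI", "CFLGI")
  if (needs_gi && is.null(gi_table))
    gi_table <- gi_table_default(design$T_total)
  cache <- if (needs_gi) cpp_flgi_cache_new() else NULL
  probs <- switch(config$rule,
    CR = function(j, counts) cr_policy(j, counts),
    TS = function(j, counts) ts_probabilities(j, counts, design, config),
    RSIHR = function(j, counts) dbcd_probabilities(j, counts, design, config),
    FLGI = function(j, counts)
      flgi_probabilities(j, counts, design, config, gi_table, seed, cache),
    CFLGI = function(j, counts)
      cflgi_probabilities(j, counts, design, config, gi_table, seed, cache))
  structure(list(rule = config$rule, config = config, design = design,
                 gi_table = gi_table, seed = as.integer(seed),
                 cache = cache, probs = probs),
            class = "rar_policy")
}

#' @export
print.rar_policy <- function(x, ...) {
  cat(sprintf("Allocation policy: %s (K = %d, T = %d)\n",
              x$rule, x$design$K, x$design$T_total))
  invisible(x)
}
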