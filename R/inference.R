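#' Pooled-variance z-test for two proportions
#'
#' The classical z-statistic
#' \eqn{z = (\hat p_1 - \hat p_0) / \sqrt{\bar p (1 - \bar p)(1/n_0 + 1/n_1)}}
#' with pooled rate \eqn{\bar p}.  Degenerate tables (a pooled rate of 0 or
#' 1, or an empty arm) yield `z = 0` and are flagged.
#'
#' @param x0,n0 successes and sample size on the control arm.
#' @param x1,n1 successes and sample size on the experimental arm.
#' @param sidedness `"one"` (alternative: experimental better) or `"two"`.
#' @param alpha nominal test level.
#' @return a `rar_test` list: `statistic`, `p_value`, `reject`,
#'   `sidedness`, `alpha`, `degenerate`.
#' @export
pooled_z_test <- function(x0, n0, x1, n1, sidedness = c("two", "one"),
                          alpha = 0.05) {
  sidedness <- match.arg(sidedness)
  degenerate <- FALSE
  if (n0 < 1 || n1 < 1) {
    z <- 0; p <- 1; degenerate <- TRUE
  } else {
    pbar <- (x0 + x1) / (n0 + n1)
    if (pbar <= 0 || pbar >= 1) {
      z <- 0
      degenerate <- TRUE
    } else {
      z <- (x1 / n1 - x0 / n0) / sqrt(pbar * (1 - pbar) * (1 / n0 + 1 / n1))
    }
    p <- if (sidedness == "one") pnorm(z, lower.tail = FALSE)
         else 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  test_result(z, p, alpha, sidedness, degenerate)
}

test_result <- function(statistic, p_value, alpha, sidedness,
                        degenerate = FALSE, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 reject = !degenerate && p_value <= alpha, alpha = alpha,
                 sidedness = sidedness, degenerate = degenerate, ...),
            class = "rar_test")
}

#' @export
print.rar_test <- function(x, ...) {
  cat(sprintf("statistic = %.4f, p = %.4g, %s-sided, %s at alpha = %g%s\n",
              x$statistic, x$p_value, x$sidedness,
              if (x$reject) "REJECT" else "do not reject", x$alpha,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test: two-sided by summing tables with probability
#' at most that observed (the default), or one-sided against the
#' alternative that the second row (the experimental arm) has the higher
#' success rate.  An empty margin gives `p = 1` with a degenerate flag.
#'
#' @param table 2x2 matrix of counts: rows = arms (control first),
#'   columns = (success, failure).
#' @param sidedness `"one"` or `"two"`.
#' @return the p-value, with attribute `degenerate`.
#' @export
fisher_exact_test <- function(table, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(structure(1, degenerate = TRUE))
  # rows reversed so alternative = "greater" means arm 1 rate > arm 0 rate
  p <- fisher.test(table[2:1, ],
                   alternative = if (sidedness == "one") "greater"
                                 else "two.sided")$p.value
  structure(min(p, 1), degenerate = FALSE)
}

#' Simulation-calibrated rejection cutoff
#'
#' Exact tests applied after an adaptive design can be badly conservative
#' at the nominal cutoff.  This helper simulates `n_sim` trials under the
#' design and the global null, computes the test's p-value for each, and
#' returns the largest cutoff `c` such that the simulated rejection
#' fraction at `p <= c` does not exceed `alpha_target` (ties resolved
#' conservatively).
#'
#' @param policy a [make_policy()] object.
#' @param null_scenario a [scenario_spec()] with all arm effects zero.
#' @param test a function `record -> p-value` (e.g. a wrapper around
#'   [fisher_exact_test()]).
#' @param n_sim number of null simulations (>= 100).
#' @param alpha_target type-I error rate to calibrate to.
#' @param seed master seed for the null simulations.
#' @return the calibrated cutoff, with attribute `null_p` (the simulated
#'   null p-values).
#' @export
calibrate_cutoff <- function(policy, null_scenario, test, n_sim = 2000,
                             alpha_target = 0.05, seed = 1L) {
  if (n_sim < 100) stop_domain("n_sim must be >= 100")
  if (any(null_scenario$params$beta_k != 0))
    stop_domain("calibration scenario must satisfy the global null")
  pv <- vapply(seq_len(n_sim), function(i) {
    rec <- run_trial(policy, null_scenario, seed = derive_seed(seed, i))
    as.numeric(test(rec))
  }, numeric(1))
  cand <- sort(unique(pv))
  frac <- vapply(cand, function(cc) mean(pv <= cc), numeric(1))
  keep <- cand[frac <= alpha_target]
  cutoff <- if (length(keep)) max(keep) else 0
  structure(cutoff, null_p = pv)
}

#' Configuration of the Monte-Carlo randomisation test
#'
#' @param M resampled trials per observed trial.
#' @param statistic `"prop_diff"` (difference in success proportions,
#'   default) or `"pooled_z"`.
#' @param sidedness `"one"` or `"two"`.
#' @param include_observed include the observed trial in the reference set
#'   (the `(1 + count) / (M + 1)` convention, guaranteeing finite-sample
#'   validity).
#' @return a `rand_test_config` list.
#' @export
rand_test_config <- function(M = 500, statistic = c("prop_diff", "pooled_z"),
                             sidedness = c("two", "one"),
                             include_observed = TRUE) {
  if (M < 1) stop_domain("M must be >= 1")
  structure(list(M = as.integer(M), statistic = match.arg(statistic),
                 sidedness = match.arg(sidedness),
                 include_observed = include_observed),
            class = "rand_test_config")
}

trial_statistic <- function(x, n, statistic) {
  if (n[1] == 0 || n[2] == 0) return(structure(0, degenerate = TRUE))
  val <- switch(statistic,
    prop_diff = x[2] / n[2] - x[1] / n[1],
    pooled_z = pooled_z_test(x[1], n[1], x[2], n[2])$statistic)
  structure(val, degenerate = FALSE)
}

#' Monte-Carlo randomisation test for an adaptive trial
#'
#' Rebuilds the null distribution of the test statistic from the
#' randomisation actually used: the observed outcomes are pinned to patient
#' positions (arm-independent under the null, whatever the time trend), and
#' `M` re-randomised trials are generated by re-running the allocation rule
#' block by block — each resample's block-`j` probabilities are computed
#' from its own re-randomised allocations and the pinned outcomes of blocks
#' `1..j-1`.  The one-sided p-value is `(1 + #{resample stat >= observed})
#' / (M + 1)`; two-sided uses `|stat|`.  This controls the type-I error for
#' any allocation rule and any time trend.
#'
#' Currently implemented for 2-arm trials (the setting where model-free
#' protection is needed; multi-arm designs protect the control allocation
#' instead).  A fast compiled resampling path is used for FLGI policies.
#'
#' @param observed a `trial_record` from [run_trial()] or
#'   [read_trial_csv()].
#' @param policy the allocation policy the trial was (or would be) run
#'   under; resampling re-runs this rule.
#' @param config a [rand_test_config()].
#' @param alpha nominal level.
#' @param seed integer seed for the resampling stream.
#' @return a `rar_test` with fields `M` and `n_degenerate` in addition to
#'   the usual ones.
#' @export
randomisation_test <- function(observed, policy, config = rand_test_config(),
                               alpha = 0.05, seed = 1L) {
  d <- attr(observed, "design")
  if (d$K != 1)
    stop_domain("the randomisation test is implemented for 2-arm trials")
  ymat <- matrix(observed$y, nrow = d$b, ncol = d$J)  # position-pinned
  xobs <- c(sum(observed$y[observed$arm == 0]), sum(observed$y[observed$arm == 1]))
  nobs <- c(sum(observed$arm == 0), sum(observed$arm == 1))
  sobs <- trial_statistic(xobs, nobs, config$statistic)

  fast <- policy$rule == "FLGI" && config$statistic == "prop_diff" &&
    d$prior_a == round(d$prior_a) && d$prior_b == round(d$prior_b)
  if (fast) {
    res <- cpp_flgi_rand_test(ymat, as.integer(d$prior_a),
                              as.integer(d$prior_b),
                              policy$config$flgi_mc_reps,
                              policy$gi_table$values, config$M,
                              as.numeric(derive_seed(seed, 7L)) * 65537 +
                                as.numeric(policy$seed),
                              policy$cache)
    stats <- res$stats
    ndegen <- res$n_degenerate
  } else {
    set.seed(derive_seed(seed, 7L))
    stats <- numeric(config$M)
    ndegen <- 0L
    for (m in seq_len(config$M)) {
      counts <- posterior_counts(d)
      x <- c(0, 0); n <- c(0, 0)
      for (j in seq_len(d$J)) {
        probs <- if (j == 1) rep(0.5, 2) else policy$probs(j, counts)
        arms <- sample.int(2, d$b, replace = TRUE, prob = probs) - 1L
        y <- ymat[, j]
        counts <- update_counts(counts, arms, y)
        x <- x + c(sum(y[arms == 0]), sum(y[arms == 1]))
        n <- n + c(sum(arms == 0), sum(arms == 1))
      }
      st <- trial_statistic(x, n, config$statistic)
      if (attr(st, "degenerate")) ndegen <- ndegen + 1L
      stats[m] <- st
    }
  }
  extra <- if (config$include_observed) 1 else 0
  denom <- config$M + extra
  p <- if (config$sidedness == "one") {
    (extra + sum(stats >= as.numeric(sobs))) / denom
  } else {
    (extra + sum(abs(stats) >= abs(as.numeric(sobs)))) / denom
  }
  out <- test_result(as.numeric(sobs), p, alpha, config$sidedness,
                     degenerate = isTRUE(attr(sobs, "degenerate")))
  out$M <- config$M
  out$n_degenerate <- ndegen
  out
}

#' Bonferroni decisions across experimental arms
#'
#' Rejects the arm-`k` null iff `p_k <= alpha_family / K`, controlling the
#' family-wise error rate at `alpha_family`.
#'
#' @param p_values per-experimental-arm p-values.
#' @param alpha_family family-wise level.
#' @return a logical vector of per-arm decisions.
#' @export
bonferroni_decide <- function(p_values, alpha_family = 0.05) {
  p_values <= alpha_family / length(p_values)
}
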