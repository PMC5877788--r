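# Hypothesis tests: pooled z, Fisher exact, calibrated cutoffs, the
# Monte-Carlo randomisation test, and Bonferroni decisions.

test_that("pooled z-test matches the hand formula", {
  # equal proportions: z = 0, two-sided p = 1, one-sided p = 0.5
  t0 <- pooled_z_test(15, 50, 30, 100)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(pooled_z_test(15, 50, 30, 100, "one")$p_value, 0.5)

  # 30/100 vs 70/100: z = 0.4 / sqrt(0.25 * 0.02)
  t1 <- pooled_z_test(30, 100, 70, 100)
  expect_equal(t1$statistic, 0.4 / sqrt(0.5 * 0.5 * 0.02), tolerance = 1e-10)
  expect_equal(t1$statistic, 5.657, tolerance = 1e-3)
  expect_true(t1$reject)

  # swapping arms negates the statistic
  t2 <- pooled_z_test(70, 100, 30, 100)
  expect_equal(t2$statistic, -t1$statistic)

  # degenerate pooled rates
  expect_true(pooled_z_test(0, 10, 0, 10)$degenerate)
  expect_true(pooled_z_test(0, 0, 5, 10)$degenerate)
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  # all-failure table has an empty success margin
  tab0 <- rbind(c(0, 8), c(0, 8))
  expect_equal(as.numeric(fisher_exact_test(tab0)), 1)
  expect_true(attr(fisher_exact_test(tab0), "degenerate"))

  # [[3,7],[7,3]]: one-sided p = P(X >= 7), X ~ Hypergeom(10, 10, 10)
  tab <- rbind(c(3, 7), c(7, 3))
  oracle <- sum(dhyper(7:10, 10, 10, 10))
  expect_equal(as.numeric(fisher_exact_test(tab, "one")), oracle,
               tolerance = 1e-12)

  # transposition invariance
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(as.numeric(fisher_exact_test(m)),
                 as.numeric(fisher_exact_test(t(m))))
    expect_equal(as.numeric(fisher_exact_test(m, "one")),
                 as.numeric(fisher_exact_test(t(m), "one")))
  }
})

test_that("cutoff calibration recovers the nominal level for uniform p-values", {
  d <- tiny_design()
  sc <- scenario1(d, p0 = 0.3, D = 0)
  pol <- make_policy("CR", d)
  # a deterministic, approximately Uniform(0,1) function of the record
  # (irrational rotation of the success count plus block-1 pattern)
  pseudo_p <- function(rec) {
    u <- sum(rec$y * seq_along(rec$y)) * pi + sum(rec$arm) * exp(1)
    u - floor(u)
  }
  cut <- calibrate_cutoff(pol, sc, pseudo_p, n_sim = 800, seed = 5)
  expect_lt(abs(as.numeric(cut) - 0.05), 0.025)

  # self-consistency: rejection rate at the returned cutoff stays at target
  pv <- attr(cut, "null_p")
  expect_lte(mean(pv <= as.numeric(cut)), 0.05)

  # monotone in the target level (same simulated nulls via the same seed)
  cut10 <- calibrate_cutoff(pol, sc, pseudo_p, n_sim = 800,
                            alpha_target = 0.10, seed = 5)
  expect_gte(as.numeric(cut10), as.numeric(cut))

  expect_error(calibrate_cutoff(pol, scenario1(d, 0.3, 0, p_arm = 0.5),
                                pseudo_p, 200), "global null")
})

test_that("randomisation test handles degenerate and extreme trials", {
  d <- tiny_design()
  pol <- make_policy("CR", d)
  sure <- scenario_spec(d, model_params(beta0 = 50))
  rec <- run_trial(pol, sure, seed = 2)
  stopifnot(all(rec$y == 1))
  res <- randomisation_test(rec, pol, rand_test_config(M = 50), seed = 3)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  expect_false(res$reject)

  # determinism: same seed, same result
  sc <- scenario1(d, p0 = 0.4, D = 0)
  rec2 <- run_trial(pol, sc, seed = 9)
  r1 <- randomisation_test(rec2, pol, rand_test_config(M = 80), seed = 13)
  r2 <- randomisation_test(rec2, pol, rand_test_config(M = 80), seed = 13)
  expect_identical(r1$p_value, r2$p_value)

  # a strong true effect is detected
  alt <- scenario1(d, p0 = 0.15, D = 0, p_arm = 0.9)
  pow <- mean(vapply(1:40, function(i) {
    r <- run_trial(pol, alt, seed = derive_seed(31, i))
    randomisation_test(r, pol, rand_test_config(M = 99),
                       seed = derive_seed(32, i))$reject
  }, logical(1)))
  expect_gt(pow, 0.6)
})

test_that("randomisation test is valid under complete randomisation with a trend", {
  # the module's central guarantee: outcomes that ignore arms, even with a
  # strong trend, reject at no more than alpha (+ 3 binomial s.e.)
  d <- tiny_design(b = 8, J = 4)
  sc <- scenario1(d, p0 = 0.25, D = 0.4)   # steep standard-of-care trend
  pol <- make_policy("CR", d)
  n_null <- 500
  rej <- vapply(seq_len(n_null), function(i) {
    rec <- run_trial(pol, sc, seed = derive_seed(7, i))
    randomisation_test(rec, pol, rand_test_config(M = 99),
                       seed = derive_seed(8, i))$reject
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / n_null))
})

test_that("Bonferroni decisions split the family-wise level", {
  expect_equal(bonferroni_decide(0.04), TRUE)
  expect_equal(bonferroni_decide(c(0.02, 0.03)), c(TRUE, FALSE))
  expect_equal(bonferroni_decide(c(1, 1, 1)), rep(FALSE, 3))
})
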