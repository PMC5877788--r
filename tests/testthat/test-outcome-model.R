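# The logistic outcome model: per-stratum rates, marginalisation over the
# covariate, trend calibration, and block sampling.

test_that("success_probability reproduces the calibrated stratum rates", {
  p <- model_params(beta0 = logit(0.3))
  expect_equal(success_probability(1, 0, 0, p), 0.3)

  p2 <- model_params(beta0 = logit(0.3), beta_z = logit(0.6) - logit(0.3))
  expect_equal(success_probability(1, 1, 0, p2), 0.6)
  expect_equal(success_probability(1, 0, 0, p2), 0.3)

  p0 <- model_params(beta0 = 0)
  expect_equal(success_probability(3, 0, 0, p0), 0.5)

  # trend enters per block with t_j = j - 1
  pt <- model_params(beta0 = logit(0.3), beta_t = 0.1)
  expect_equal(success_probability(1, 0, 0, pt), 0.3)
  expect_equal(success_probability(4, 0, 0, pt), expit(logit(0.3) + 0.3))

  expect_error(success_probability(0, 0, 0, p), "block index")
  expect_error(success_probability(6, 0, 0, p, J = 5), "block index")
  expect_error(success_probability(1, 0, 2, p), "arm index")
  expect_error(success_probability(1, 2, 0, p), "z must be")
})

test_that("marginal_rate mixes strata by the covariate prevalence", {
  p <- model_params(beta0 = logit(0.3), beta_z = logit(0.6) - logit(0.3))
  # degenerate mixtures reduce to the stratum rates
  expect_equal(marginal_rate(1, 0, p, covariate_path(rep(0, 3))), 0.3)
  expect_equal(marginal_rate(1, 0, p, covariate_path(rep(1, 3))), 0.6)
  # half-and-half mixture of 0.3 and 0.6
  expect_equal(marginal_rate(2, 0, p, covariate_path(rep(0.5, 3))), 0.45)

  # marginal_rate equals the Bernoulli mixture of success_probability for
  # random parameter draws
  set.seed(41)
  for (i in 1:200) {
    pp <- model_params(beta0 = rnorm(1), beta_t = rnorm(1, 0, 0.2),
                       beta_z = rnorm(1), beta_k = rnorm(1))
    q <- covariate_path(runif(4))
    j <- sample.int(4, 1); k <- sample(0:1, 1)
    mix <- (1 - q$q[j]) * success_probability(j, 0, k, pp) +
      q$q[j] * success_probability(j, 1, k, pp)
    expect_equal(marginal_rate(j, k, pp, q), mix, tolerance = 1e-12)
  }
})

test_that("mean_rate averages blocks and matches the drifting-mix value", {
  p <- model_params(beta0 = logit(0.3), beta_z = logit(0.6) - logit(0.3))
  q <- linear_q_path(0.5, 0.05, 10)
  # mean prevalence 0.725: 0.275 * 0.3 + 0.725 * 0.6
  expect_equal(mean_rate(0, p, q), 0.5175, tolerance = 1e-12)

  # constant marginal rates give back the constant
  expect_equal(mean_rate(0, model_params(beta0 = logit(0.3)),
                         covariate_path(rep(0, 5))), 0.3)

  # without a trend, mean_rate is invariant to permuting blocks
  set.seed(7)
  qperm <- sample(q$q)
  expect_equal(mean_rate(0, p, covariate_path(qperm)), mean_rate(0, p, q))
})

test_that("solve_beta_t satisfies the drift definition in closed form", {
  expect_equal(solve_beta_t(0, 0.3, 5), 0)
  expect_equal(solve_beta_t(0.24, 0.3, 5), 0.2519, tolerance = 5e-5)
  expect_equal(solve_beta_t(0.3, 0.3, 2), logit(0.6) - logit(0.3))

  # round trip: plugging beta_t back into the drift definition recovers D
  set.seed(11)
  for (i in 1:100) {
    p0 <- runif(1, 0.05, 0.6); D <- runif(1, 0, 0.95 - p0)
    J <- sample(2:12, 1)
    bt <- solve_beta_t(D, p0, J)
    expect_equal(expit(logit(p0) + bt * (J - 1)) - p0, D, tolerance = 1e-10)
  }
  expect_error(solve_beta_t(0.8, 0.3, 5), "p0")
  expect_error(solve_beta_t(0.1, 0, 5), "p0")
})

test_that("risk_difference mode keeps the arm effect exact on the probability scale", {
  d <- design_spec(K = 2, T_total = 200, J = 10, b = 20)
  sc <- scenario2(d, arm_effect = c(0.2, 0))
  rates <- arm_mean_rates(sc)
  expect_equal(rates[2] - rates[1], 0.2, tolerance = 1e-12)
  expect_equal(rates[3], rates[1])
  expect_equal(best_arm(sc), 1L)
  # logit-additive mode does not preserve the probability-scale difference
  sc_l <- scenario2(d, arm_effect = c(logit(0.5) - logit(0.3), 0),
                    effect_mode = "logit_additive")
  r_l <- arm_mean_rates(sc_l)
  expect_false(isTRUE(all.equal(r_l[2] - r_l[1], 0.2, tolerance = 1e-3)))
})

test_that("sample_block respects the allocation distribution and is reproducible", {
  d <- design_spec(K = 2, T_total = 60, J = 3, b = 20)
  sc <- scenario1(d, p0 = 0.3, D = 0)

  set.seed(5)
  blk <- sample_block(1, c(1, 0, 0), sc)
  expect_true(all(blk$arm == 0))

  sure <- scenario_spec(d, model_params(beta0 = 50, beta_k = c(0, 0)))
  set.seed(5)
  expect_true(all(sample_block(1, rep(1 / 3, 3), sure)$y == 1))

  set.seed(9); b1 <- sample_block(2, c(0.2, 0.3, 0.5), sc)
  set.seed(9); b2 <- sample_block(2, c(0.2, 0.3, 0.5), sc)
  expect_identical(b1, b2)

  expect_error(sample_block(1, c(0.5, 0.4, 0.2), sc), "simplex")

  # empirical allocation frequencies match probs within 3 MC s.e.
  dbig <- design_spec(K = 2, T_total = 3e4, J = 1, b = 3e4)
  scbig <- scenario1(dbig, p0 = 0.3, D = 0)
  set.seed(13)
  blk <- sample_block(1, c(0.2, 0.3, 0.5), scbig)
  freq <- tabulate(blk$arm + 1, 3) / nrow(blk)
  se <- sqrt(c(0.2, 0.3, 0.5) * c(0.8, 0.7, 0.5) / 3e4)
  expect_true(all(abs(freq - c(0.2, 0.3, 0.5)) < 3 * se))
})
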