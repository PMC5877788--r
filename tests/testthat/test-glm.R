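# Model-based analysis: maximum-likelihood and Firth-penalised logistic
# regression, separation handling, and the Jeffreys closed form.

make_record <- function(arm, y, z = 0, block = 1, K = max(arm)) {
  rec <- data.frame(block = block, patient_in_block = seq_along(arm),
                    arm = arm, z = z, y = y)
  attr(rec, "design") <- design_spec(K = K, T_total = length(arm), J = 1,
                                     b = length(arm))
  attr(rec, "z_observed") <- TRUE
  class(rec) <- c("trial_record", "data.frame")
  rec
}

test_that("ML fit recovers the generating parameters on large CR data", {
  d <- design_spec(K = 1, T_total = 4000, J = 5, b = 800)
  sc <- scenario_spec(d, model_params(beta0 = logit(0.3), beta_t = 0.2,
                                      beta_z = logit(0.6) - logit(0.3),
                                      beta_k = 0.5),
                      q_path = covariate_path(rep(0.5, 5)),
                      z_observed = TRUE)
  rec <- run_trial(make_policy("CR", d), sc, seed = 17)
  fit <- fit_logistic_ml(rec, terms = c("t", "z", "arm"))
  expect_false(fit$separation)
  truth <- c(logit(0.3), 0.2, logit(0.6) - logit(0.3), 0.5)
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$se))
})

test_that("separation is flagged by ML and resolved by Firth", {
  # one arm with few, all-failure observations: quasi-complete separation
  rec <- make_record(arm = rep(c(0, 1), c(8, 5)),
                     y = c(1, 1, 1, 0, 1, 0, 1, 1, rep(0, 5)))
  ml <- fit_logistic_ml(rec, terms = "arm")
  expect_true(ml$separation)

  fi <- fit_logistic_firth(rec, terms = "arm")
  expect_true(all(is.finite(fi$coefficients$estimate)))
  expect_true(fi$converged)

  # 5/5 successes vs 0/5: complete separation, Firth still finite
  rec2 <- make_record(arm = rep(c(0, 1), each = 5), y = rep(c(1, 0), each = 5))
  expect_true(fit_logistic_ml(rec2, terms = "arm")$separation)
  fi2 <- fit_logistic_firth(rec2, terms = "arm")
  expect_true(all(is.finite(fi2$coefficients$estimate)))

  # all outcomes identical: degenerate, no fit
  rec3 <- make_record(arm = rep(c(0, 1), each = 5), y = rep(1, 10))
  expect_true(fit_logistic_ml(rec3, terms = "arm")$degenerate)
  expect_true(fit_logistic_firth(rec3, terms = "arm")$degenerate)
})

test_that("Firth fit matches the Jeffreys closed form and symmetry", {
  # intercept-only model: estimate is logit((x + 1/2) / (n + 1))
  for (case in list(c(3, 10), c(1, 12), c(9, 11))) {
    x <- case[1]; n <- case[2]
    rec <- make_record(arm = rep(0, n), y = rep(c(1, 0), c(x, n - x)), K = 1)
    fit <- fit_logistic_firth(rec, terms = character(0))
    expect_equal(fit$coefficients$estimate[1],
                 logit((x + 0.5) / (n + 1)), tolerance = 1e-6)
  }

  # balanced symmetric data: the arm coefficient vanishes
  rec <- make_record(arm = rep(c(0, 1), each = 10),
                     y = rep(c(1, 0, 1, 0), each = 5))
  fit <- fit_logistic_firth(rec, terms = "arm")
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-6)

  # penalty vanishes asymptotically: ML and Firth agree on large data
  set.seed(23)
  n <- 12000
  arm <- rep(c(0, 1), each = n / 2)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * arm))
  big <- make_record(arm = arm, y = y)
  ml <- fit_logistic_ml(big, terms = "arm")
  fi <- fit_logistic_firth(big, terms = "arm")
  expect_true(all(abs(ml$coefficients$estimate -
                        fi$coefficients$estimate) < 0.01))
})

test_that("Firth estimates stay finite wherever ML flags separation", {
  set.seed(29)
  n_sep <- 0
  for (i in 1:200) {
    n <- sample(8:16, 1)
    arm <- rbinom(n, 1, 0.5)
    if (length(unique(arm)) < 2) next
    y <- rbinom(n, 1, 0.3 + 0.4 * arm)
    if (all(y == y[1])) next
    rec <- make_record(arm = arm, y = y)
    ml <- fit_logistic_ml(rec, terms = "arm")
    if (ml$separation) {
      n_sep <- n_sep + 1
      fi <- fit_logistic_firth(rec, terms = "arm")
      expect_true(all(is.finite(fi$coefficients$estimate)))
      expect_true(all(is.finite(fi$coefficients$p_value)))
    }
  }
  expect_gt(n_sep, 5)  # the fuzz must actually exercise separation
})

test_that("covariate adjustment requires the covariate to be observed", {
  d <- tiny_design()
  sc <- scenario1(d, p0 = 0.4, D = 0)   # scenario-1 records flag z unobserved
  rec <- run_trial(make_policy("CR", d), sc, seed = 3)
  expect_error(fit_logistic_ml(rec, terms = c("z", "arm")), "unobserved")
})
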