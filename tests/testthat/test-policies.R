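# The five block-wise allocation rules.

test_that("complete randomisation is uniform and data-independent", {
  d2 <- tiny_design(K = 1)
  d3 <- tiny_design(K = 2)
  expect_equal(cr_policy(1, posterior_counts(d2)), c(0.5, 0.5))
  expect_equal(cr_policy(1, posterior_counts(d3)), rep(1 / 3, 3))
  set.seed(2)
  expect_equal(cr_policy(4, random_counts(3)), rep(1 / 3, 3))
})

test_that("prob_best matches the closed-form Beta comparison", {
  # P(p1 > p0) for Beta(2,1) vs Beta(1,2) is 5/6
  cnt <- structure(list(s = c(1, 2), f = c(2, 1), n = c(1, 1)),
                   class = "posterior_counts")
  set.seed(3)
  pb <- prob_best(cnt, mc_draws = 4e4)
  se <- sqrt(5 / 6 * 1 / 6 / 4e4)
  expect_equal(sum(pb), 1)
  expect_lt(abs(pb[2] - 5 / 6), 3 * se)

  sym <- structure(list(s = c(2, 2), f = c(3, 3), n = c(3, 3)),
                   class = "posterior_counts")
  set.seed(4)
  expect_lt(abs(prob_best(sym, 4e4)[1] - 0.5), 3 * sqrt(0.25 / 4e4))

  tri <- structure(list(s = rep(1, 3), f = rep(1, 3), n = rep(0, 3)),
                   class = "posterior_counts")
  set.seed(5)
  expect_true(all(abs(prob_best(tri, 4e4) - 1 / 3) < 3 * sqrt(2 / 9 / 4e4)))
})

test_that("tuned Thompson sampling starts uniform and sharpens with data", {
  d <- design_spec(K = 1, T_total = 100, J = 5, b = 20)
  skew <- structure(list(s = c(4, 8), f = c(8, 4), n = c(10, 10)),
                    class = "posterior_counts")
  set.seed(6)
  expect_equal(ts_probabilities(1, skew, d), c(0.5, 0.5))  # c = 0 at j = 1

  # exponent 1 is the identity on prob_best weights; c = 0 is uniform;
  # large c approaches a point mass
  expect_equal(driftrar:::ts_alloc_weights(c(5 / 6, 1 / 6), 1),
               c(5 / 6, 1 / 6))
  expect_equal(driftrar:::ts_alloc_weights(c(0.9, 0.1), 0), c(0.5, 0.5))
  expect_equal(driftrar:::ts_alloc_weights(c(0.9, 0.1), 200), c(1, 0),
               tolerance = 1e-12)

  sym <- structure(list(s = c(5, 5), f = c(5, 5), n = c(8, 8)),
                   class = "posterior_counts")
  set.seed(7)
  p <- ts_probabilities(3, sym, d)
  expect_lt(abs(p[1] - 0.5), 0.02)  # symmetry, within MC error

  # later blocks skew harder toward the posterior-best arm
  set.seed(8); p2 <- ts_probabilities(2, skew, d)
  set.seed(8); p5 <- ts_probabilities(5, skew, d)
  expect_gt(p5[2], p2[2])
})

test_that("RSIHR target follows the square-root optimal allocation", {
  expect_equal(rsihr_target(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(rsihr_target(c(0.1, 0.9))[2],
               sqrt(0.9) / (sqrt(0.9) + sqrt(0.1)), tolerance = 1e-12)
  expect_equal(rsihr_target(c(0.1, 0.9))[2], 0.75, tolerance = 1e-4)

  # plain-ratio variant
  cfg <- policy_config("RSIHR", rsihr_form = "ratio")
  expect_equal(rsihr_target(c(0.2, 0.6), cfg)[2], 0.75)

  # rho_1 increases in p_1 and stays on the simplex
  grid <- seq(0.05, 0.95, by = 0.05)
  rho1 <- vapply(grid, function(p1) rsihr_target(c(0.3, p1))[2], numeric(1))
  expect_true(all(diff(rho1) > 0))
  expect_true(all(rho1 > 0 & rho1 < 1))

  expect_warning(rsihr_target(c(0, 0.5)), "clamped")

  # multi-arm numerical target: simplex, floor, favours the better arms
  rho <- rsihr_target(c(0.3, 0.7, 0.3))
  expect_equal(sum(rho), 1, tolerance = 1e-8)
  expect_true(all(rho >= 0.05 - 1e-8))
  expect_gt(rho[2], rho[3])
})

test_that("DBCD pushes allocation toward the target with exponent gamma", {
  d <- tiny_design(K = 1)
  cfg <- policy_config("RSIHR", gamma = 2)

  # fixed point: x = rho leaves the probabilities at rho
  cnt <- structure(list(s = c(4, 7), f = c(8, 4), n = c(50, 50)),
                   class = "posterior_counts")
  rho <- rsihr_target(c(0.5, 0.5))
  p <- dbcd_probabilities(2, cnt, d, cfg, p_hat = c(0.5, 0.5))
  expect_equal(p, rho)

  # hand-computed value: rho = (.6, .4), x = (.5, .5), gamma = 2
  cnt2 <- structure(list(s = c(2, 2), f = c(2, 2), n = c(25, 25)),
                    class = "posterior_counts")
  p_hat <- c(0.36, 0.81)  # sqrt targets (0.4, 0.6)
  p2 <- dbcd_probabilities(2, cnt2, d, cfg, p_hat = p_hat)
  expect_equal(p2, c(0.4 * 0.64, 0.6 * 1.44) / (0.4 * 0.64 + 0.6 * 1.44),
               tolerance = 1e-10)
  expect_equal(p2[1], 0.2286, tolerance = 1e-3)

  # before any data the prior means give a uniform target, returned directly
  expect_equal(dbcd_probabilities(1, posterior_counts(d), d, cfg),
               c(0.5, 0.5))
})

test_that("FLGI probabilities match exhaustive rollout enumeration", {
  tab <- gi_small()
  d <- design_spec(K = 1, T_total = 8, J = 4, b = 2)

  # identical states: exact symmetry
  cnt <- posterior_counts(d)
  p <- flgi_probabilities(2, cnt, d, policy_config("FLGI"), tab)
  expect_identical(p, c(0.5, 0.5))

  # dominant arm: GI monotonicity keeps arm 1 maximal along every path
  cnt2 <- structure(list(s = c(1, 2), f = c(2, 1), n = c(2, 2)),
                    class = "posterior_counts")
  expect_identical(
    flgi_probabilities(2, cnt2, d, policy_config("FLGI"), tab), c(0, 1))

  # exhaustive-path oracle for b = 2 and b = 3
  for (case in list(list(s = c(2, 2), f = c(3, 2), b = 2),
                    list(s = c(3, 2), f = c(2, 2), b = 3),
                    list(s = c(2, 3, 2), f = c(2, 2, 3), b = 3))) {
    exact <- flgi_exact(case$s, case$f, case$b, tab)
    dd <- design_spec(K = length(case$s) - 1, T_total = case$b * 2, J = 2,
                      b = case$b)
    cc <- structure(list(s = case$s, f = case$f, n = case$s + case$f - 2),
                    class = "posterior_counts")
    est <- flgi_probabilities(2, cc, dd,
                              policy_config("FLGI", flgi_mc_reps = 2e4),
                              tab, seed = 17)
    expect_true(all(abs(est - exact) < 3 * sqrt(pmax(exact * (1 - exact),
                                                     0.01) / 2e4) + 1e-3),
                info = paste("state", paste(case$s, case$f, collapse = "/")))
  }

  # b = 1: probability that each arm attains the maximal index
  cnt3 <- structure(list(s = c(2, 1), f = c(1, 1), n = c(1, 0)),
                    class = "posterior_counts")
  d1 <- design_spec(K = 1, T_total = 4, J = 4, b = 1)
  expect_identical(
    flgi_probabilities(2, cnt3, d1, policy_config("FLGI"), tab), c(1, 0))
})

test_that("CFLGI pins the control share and redistributes by FLGI", {
  tab <- gi_small()
  d <- design_spec(K = 2, T_total = 12, J = 4, b = 3)
  cfg <- policy_config("CFLGI")

  set.seed(10)
  for (i in 1:20) {
    cnt <- random_counts(3, max_n = 5)
    p <- cflgi_probabilities(2, cnt, d, cfg, tab, seed = i)
    expect_equal(p[1], 1 / 3)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }

  # symmetric experimental arms share the remainder equally (exact)
  cnt_sym <- posterior_counts(d)
  expect_equal(cflgi_probabilities(2, cnt_sym, d, cfg, tab),
               c(1 / 3, 1 / 3, 1 / 3))

  # dominant experimental arm absorbs the experimental mass
  cnt_dom <- structure(list(s = c(3, 9, 2), f = c(3, 2, 9), n = c(4, 9, 9)),
                       class = "posterior_counts")
  p <- cflgi_probabilities(2, cnt_dom, d, cfg, tab, seed = 3)
  expect_equal(p[1], 1 / 3)
  expect_gt(p[2], 0.6)
  expect_lt(p[3], 0.05)

  # experimental sub-vector rescaled by (K+1)/K equals FLGI on the
  # experimental arms alone with the same seed
  sub <- structure(list(s = cnt_dom$s[-1], f = cnt_dom$f[-1],
                        n = cnt_dom$n[-1]), class = "posterior_counts")
  pf <- flgi_probabilities(2, sub, d, policy_config("FLGI"), tab, seed = 3)
  expect_equal(p[-1] * 3 / 2, pf, tolerance = 1e-12)
})

test_that("every policy's output lies on the probability simplex", {
  tab <- gi_small()
  d2 <- design_spec(K = 1, T_total = 16, J = 4, b = 4)
  d3 <- design_spec(K = 2, T_total = 15, J = 5, b = 3)
  pols <- list(
    CR = make_policy("CR", d3),
    TS = make_policy("TS", d2, ts_mc_draws = 500),
    RSIHR = make_policy("RSIHR", d3),
    FLGI = make_policy("FLGI", d2, gi_table = tab),
    CFLGI = make_policy("CFLGI", d3, gi_table = tab))
  set.seed(12)
  for (nm in names(pols)) {
    pol <- pols[[nm]]
    narms <- pol$design$K + 1
    for (i in 1:40) {
      cnt <- random_counts(narms, max_n = 4)
      p <- pol$probs(2, cnt)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_true(all(p >= 0 & p <= 1), info = nm)
    }
  }
})
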