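#' Trial design skeleton
#'
#' Defines the block-randomised trial frame shared by every allocation rule
#' and scenario: `K` experimental arms plus a control (arm 0), `T = b * J`
#' patients enrolled in `J` blocks of size `b`, and the Beta prior
#' pseudo-counts placed on every arm's success rate (uniform Beta(1, 1) by
#' default).
#'
#' @param K number of experimental arms (control is arm 0), `K >= 1`.
#' @param T_total total trial size; must equal `b * J`.
#' @param J number of blocks (interim updates happen between blocks).
#' @param b block size.
#' @param prior_a,prior_b Beta prior pseudo-counts per arm (must be > 0).
#' @return an object of class `design_spec`.
#' @examples
#' design_spec(K = 1, T_total = 100, J = 5, b = 20)
#' @export
design_spec <- function(K, T_total, J, b, prior_a = 1, prior_b = 1) {
  if (K < 1) stop_domain("K must be >= 1")
  if (b < 1 || J < 1) stop_domain("b and J must be >= 1")
  if (T_total != b * J)
    stop_domain("T_total must equal b * J (got T=", T_total,
                ", b*J=", b * J, ")")
  if (prior_a <= 0 || prior_b <= 0)
    stop_domain("prior pseudo-counts must be positive")
  structure(list(K = as.integer(K), T_total = as.integer(T_total),
                 J = as.integer(J), b = as.integer(b),
                 prior_a = prior_a, prior_b = prior_b),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Trial design: %d arm(s) + control, T = %d = %d blocks x %d, Beta(%g, %g) priors\n",
              x$K, x$T_total, x$J, x$b, x$prior_a, x$prior_b))
  invisible(x)
}

#' Outcome-model parameters
#'
#' Coefficients of the logistic data-generating model for a binary outcome:
#' \deqn{\mathrm{logit}\,\Pr(Y_{i,j,k}=1 \mid Z_{i,j}, a_{i,j,k}=1) =
#'   \beta_0 + \beta_t t_j + \beta_z Z_{i,j} + \beta_k \mathbf{1}\{k \ge 1\}}
#' with block time `t_j = j - 1`.  Two effect parameterisations are
#' supported: `"logit_additive"` adds `beta_k` on the log-odds scale (the
#' model above, literally); `"risk_difference"` interprets `beta_k[k]` as a
#' constant probability-scale increment added to the control success rate
#' (clamped to `[0, 1]`), which keeps the arm-vs-control risk difference
#' exactly constant under drift.
#'
#' @param beta0 baseline log-odds.
#' @param beta_t per-block time-trend log-odds.
#' @param beta_z covariate (e.g. biomarker) log-odds.
#' @param beta_k numeric vector of `K` arm effects (arm 1..K); under the
#'   global null all zero.
#' @param effect_mode `"logit_additive"` or `"risk_difference"`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(beta0, beta_t = 0, beta_z = 0, beta_k = 0,
                         effect_mode = c("logit_additive", "risk_difference")) {
  effect_mode <- match.arg(effect_mode)
  structure(list(beta0 = beta0, beta_t = beta_t, beta_z = beta_z,
                 beta_k = as.numeric(beta_k), effect_mode = effect_mode),
            class = "model_params")
}

#' Covariate-prevalence path
#'
#' Per-block probability that a patient carries the covariate,
#' `Z_{i,j} ~ Bern(q_j)`.  A drifting path (e.g. `q_j = 0.5 + 0.05 (j-1)`)
#' models patient drift: the mix of recruited patients changes over the
#' trial.
#'
#' @param q numeric vector of length `J`, each element in `[0, 1]`.
#' @return an object of class `covariate_path`.
#' @seealso [linear_q_path()]
#' @export
covariate_path <- function(q) {
  q <- as.numeric(q)
  if (any(q < 0 | q > 1)) stop_domain("all q_j must lie in [0, 1]")
  structure(list(q = q, J = length(q)), class = "covariate_path")
}

#' @param start,step first value and per-block increment of a linear path.
#' @param J number of blocks.
#' @rdname covariate_path
#' @export
linear_q_path <- function(start, step, J) covariate_path(start + step * (seq_len(J) - 1))

#' Solve the time-trend coefficient for a target overall drift
#'
#' The overall drift `D` is defined on the probability scale as the change in
#' the control (covariate-negative) success rate between the first and the
#' last block: `D = Expit(beta0 + beta_t (J - 1)) - Expit(beta0)` with
#' `beta0 = logit(p0)`.  The closed-form solution is
#' `beta_t = (logit(p0 + D) - logit(p0)) / (J - 1)`.
#'
#' @param D overall trend magnitude on the probability scale.
#' @param p0 baseline (block 1) success rate.
#' @param J number of blocks (`J >= 2`).
#' @return the per-block log-odds trend `beta_t`.
#' @examples
#' solve_beta_t(0.24, 0.3, 5)  # 0.2519
#' @export
solve_beta_t <- function(D, p0, J) {
  if (J < 2) stop_domain("J must be >= 2")
  if (p0 <= 0 || p0 + D >= 1)
    stop_domain("need 0 < p0 and p0 + D < 1")
  if (p0 + D <= 0) stop_domain("p0 + D must be positive")
  (logit(p0 + D) - logit(p0)) / (J - 1)
}

#' Per-stratum success probability
#'
#' Success probability of a patient in block `j` with covariate value `z`
#' allocated to arm `k`, under the logistic outcome model.
#'
#' @param j block index (1-based; time enters as `t_j = j - 1`).
#' @param z covariate value, 0 or 1.
#' @param k arm index, 0 (control) to `K`.
#' @param params a [model_params()] object.
#' @param J upper bound for `j` (optional; pass the design's `J` to enforce
#'   the block range).
#' @return a probability (vectorised over `j`, `z`, `k`).
#' @examples
#' p <- model_params(beta0 = logit(0.3))
#' success_probability(1, 0, 0, p)  # 0.3
#' @export
success_probability <- function(j, z, k, params, J = Inf) {
  K <- length(params$beta_k)
  if (any(j < 1) || any(j > J) || any(j != floor(j)))
    stop_domain("block index j must be an integer in 1..J")
  if (any(!z %in% c(0, 1))) stop_domain("z must be 0 or 1")
  if (any(k < 0) || any(k > K)) stop_domain("arm index k must lie in 0..K")
  eta0 <- params$beta0 + params$beta_t * (j - 1) + params$beta_z * z
  if (params$effect_mode == "logit_additive") {
    expit(eta0 + ifelse(k >= 1, params$beta_k[pmax(k, 1)], 0))
  } else {
    pmin(pmax(expit(eta0) + ifelse(k >= 1, params$beta_k[pmax(k, 1)], 0), 0), 1)
  }
}

#' Marginal and mean response rates
#'
#' `marginal_rate()` marginalises the per-stratum success probability over
#' the covariate, `Z ~ Bern(q_j)`:
#' `Expit(beta0 + beta_t t_j)(1 - q_j) + Expit(beta0 + beta_t t_j + beta_z) q_j`
#' (plus the arm effect for `k >= 1`).  `mean_rate()` is its arithmetic mean
#' over blocks `j = 1..J`, the quantity patients on arm `k` experience on
#' average over the whole trial.
#'
#' @inheritParams success_probability
#' @param q_path a [covariate_path()] object.
#' @return a probability.
#' @examples
#' p <- model_params(beta0 = logit(0.3), beta_z = logit(0.6) - logit(0.3))
#' q <- linear_q_path(0.5, 0.05, 10)
#' mean_rate(0, p, q)  # 0.5175
#' @export
marginal_rate <- function(j, k, params, q_path) {
  if (any(j < 1) || any(j > q_path$J))
    stop_domain("block index j must lie in 1..J")
  q <- q_path$q[j]
  (1 - q) * success_probability(j, 0, k, params) +
    q * success_probability(j, 1, k, params)
}

#' @rdname marginal_rate
#' @export
mean_rate <- function(k, params, q_path) {
  mean(marginal_rate(seq_len(q_path$J), k, params, q_path))
}

#' Trial scenario
#'
#' Binds a [design_spec()], [model_params()] and [covariate_path()] into a
#' complete data-generating scenario.  If `D` is supplied (and `beta_t` is
#' not already set), the time-trend coefficient is solved with
#' [solve_beta_t()] on the control, covariate-negative success curve.
#'
#' Two canonical constructors cover the study conditions:
#' * [scenario1()] — *changes in the standard of care*: a log-odds time
#'   trend `beta_t != 0` shared by all arms, no covariate (`beta_z = 0`).
#' * [scenario2()] — *patient drift*: no explicit time trend
#'   (`beta_t = 0`), but a prognostic covariate with effect `beta_z` whose
#'   prevalence `q_j` evolves over blocks.
#'
#' @param design a [design_spec()].
#' @param params a [model_params()].
#' @param q_path a [covariate_path()] of length `J` (defaults to all-zero
#'   prevalence, i.e. no covariate).
#' @param D optional overall drift magnitude used to solve `beta_t`.
#' @param label scenario label (`"scenario1"`, `"scenario2"`, `"custom"`).
#' @param z_observed whether the covariate is recorded as observable for
#'   inference (model-based analyses may only adjust for `Z` when `TRUE`).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(design, params, q_path = NULL, D = NULL,
                          label = c("custom", "scenario1", "scenario2"),
                          z_observed = FALSE) {
  label <- match.arg(label)
  stopifnot(inherits(design, "design_spec"), inherits(params, "model_params"))
  if (is.null(q_path)) q_path <- covariate_path(rep(0, design$J))
  if (q_path$J != design$J)
    stop_domain("q_path length (", q_path$J, ") must equal J (", design$J, ")")
  if (length(params$beta_k) != design$K)
    stop_domain("beta_k must have length K = ", design$K)
  if (!is.null(D)) {
    p0 <- expit(params$beta0)
    params$beta_t <- if (D == 0) 0 else solve_beta_t(D, p0, design$J)
  }
  if (label == "scenario1" && params$beta_z != 0)
    stop_domain("scenario 1 requires beta_z = 0")
  if (label == "scenario2" && params$beta_t != 0)
    stop_domain("scenario 2 requires beta_t = 0")
  structure(list(design = design, params = params, q_path = q_path,
                 D = D %||% NA_real_, label = label, z_observed = z_observed),
            class = "scenario_spec")
}

#' @param p0 baseline (block 1) control success rate.
#' @param p_arm success rates of the experimental arms in block 1 (length
#'   `K`); defaults to `p0` (global null).  Effects enter on the log-odds
#'   scale: `beta_k = logit(p_arm) - logit(p0)`.
#' @rdname scenario_spec
#' @export
scenario1 <- function(design, p0 = 0.3, D = 0, p_arm = NULL) {
  p_arm <- p_arm %||% rep(p0, design$K)
  if (length(p_arm) == 1) p_arm <- rep(p_arm, design$K)
  params <- model_params(beta0 = logit(p0),
                         beta_k = logit(p_arm) - logit(p0))
  scenario_spec(design, params, D = D, label = "scenario1")
}

#' @param p_neg,p_pos success rates of covariate-negative / -positive
#'   patients on the control arm (`beta_z = logit(p_pos) - logit(p_neg)`).
#' @param q a [covariate_path()] (defaults to the drifting prevalence
#'   `q_j = 0.5 + 0.05 (j - 1)`).
#' @param arm_effect arm effects, length `K`; interpreted per `effect_mode`.
#' @param effect_mode see [model_params()]; the default
#'   `"risk_difference"` keeps the arm-vs-control effect constant on the
#'   probability scale across the drifting patient mix.
#' @rdname scenario_spec
#' @export
scenario2 <- function(design, p_neg = 0.3, p_pos = 0.6, q = NULL,
                      arm_effect = 0,
                      effect_mode = c("risk_difference", "logit_additive"),
                      z_observed = TRUE) {
  effect_mode <- match.arg(effect_mode)
  q <- q %||% linear_q_path(0.5, 0.05, design$J)
  if (length(arm_effect) == 1) arm_effect <- rep(arm_effect, design$K)
  params <- model_params(beta0 = logit(p_neg),
                         beta_z = logit(p_pos) - logit(p_neg),
                         beta_k = arm_effect, effect_mode = effect_mode)
  scenario_spec(design, params, q_path = q, label = "scenario2",
                z_observed = z_observed)
}

#' @export
print.scenario_spec <- function(x, ...) {
  print(x$design)
  cat(sprintf("%s: beta0 = %.4f, beta_t = %.4f, beta_z = %.4f, beta_k = (%s) [%s]\n",
              x$label, x$params$beta0, x$params$beta_t, x$params$beta_z,
              paste(sprintf("%.4f", x$params$beta_k), collapse = ", "),
              x$params$effect_mode))
  if (any(x$q_path$q > 0))
    cat("  q_j:", paste(sprintf("%.2f", x$q_path$q), collapse = " "), "\n")
  invisible(x)
}

#' True mean response rate per arm
#'
#' `arm_mean_rates()` returns [mean_rate()] for every arm `0..K`;
#' `best_arm()` is the arm with the largest mean rate (the reference arm,
#' arm 1, under the global null where all arms tie).
#'
#' @param scenario a [scenario_spec()].
#' @return `arm_mean_rates()`: numeric vector of length `K + 1` (arms
#'   `0..K`); `best_arm()`: a single arm index.
#' @export
arm_mean_rates <- function(scenario) {
  vapply(0:scenario$design$K, mean_rate, numeric(1),
         params = scenario$params, q_path = scenario$q_path)
}

#' @rdname arm_mean_rates
#' @export
best_arm <- function(scenario) {
  rates <- arm_mean_rates(scenario)
  if (max(rates) - min(rates) < 1e-12) return(1L)  # null: reference arm
  which.max(rates) - 1L
}
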