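#' Model-based analysis of a trial record
#'
#' Fits the logistic outcome model to per-patient trial data, with terms
#' chosen from the block time trend (`t = j - 1`), the patient covariate
#' `z`, and arm indicator variables.  `fit_logistic_ml()` uses standard
#' maximum likelihood (via [stats::glm()]) with Wald p-values and flags
#' complete or quasi-complete separation — a real hazard after
#' patient-benefit-oriented adaptive allocation, where an arm can be
#' dropped early with few, all-failure observations.  `fit_logistic_firth()`
#' maximises the Jeffreys-penalised likelihood
#' \eqn{\ell(\beta) + \frac12 \log \det I(\beta)} (Firth's correction),
#' which keeps every estimate finite under separation; its p-values come
#' from penalised likelihood-ratio tests.
#'
#' @param records a `trial_record` (or `rbind` of several).
#' @param terms subset of `c("t", "z", "arm")` to include besides the
#'   intercept.
#' @param divergence_bound absolute coefficient size beyond which an ML fit
#'   is flagged as separated.
#' @return a `glm_fit` list: `coefficients` (data frame with `estimate`,
#'   `se`, `p_value`), `converged`, `separation`, `degenerate`,
#'   `penalised`.
#' @export
fit_logistic_ml <- function(records, terms = c("t", "z", "arm"),
                            divergence_bound = 15) {
  dm <- build_design_matrix(records, terms)
  if (dm$degenerate)
    return(glm_fit_degenerate(dm, penalised = FALSE))
  fit <- suppressWarnings(glm.fit(dm$X, dm$y, family = binomial()))
  est <- fit$coefficients
  # Wald SEs from the final IRLS weights
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  info <- crossprod(dm$X * W, dm$X)
  vc <- try(solve(info), silent = TRUE)
  singular <- inherits(vc, "try-error")
  se <- if (singular) rep(Inf, length(est)) else sqrt(pmax(diag(vc), 0))
  zval <- est / se
  pval <- 2 * pnorm(abs(zval), lower.tail = FALSE)
  separation <- singular || !fit$converged ||
    any(abs(est) > divergence_bound) || any(!is.finite(est))
  structure(list(
    coefficients = data.frame(term = colnames(dm$X), estimate = est,
                              se = se, p_value = pval, row.names = NULL),
    converged = fit$converged && !separation,
    separation = separation, degenerate = FALSE, penalised = FALSE),
    class = "glm_fit")
}

#' @rdname fit_logistic_ml
#' @param max_iter,tol Newton iteration controls for the penalised fit.
#' @export
fit_logistic_firth <- function(records, terms = c("t", "z", "arm"),
                               max_iter = 50, tol = 1e-6) {
  dm <- build_design_matrix(records, terms)
  if (dm$degenerate)
    return(glm_fit_degenerate(dm, penalised = TRUE))
  full <- firth_newton(dm$X, dm$y, max_iter = max_iter, tol = tol)
  p <- ncol(dm$X)
  pval <- vapply(seq_len(p), function(jj) {
    red <- firth_newton(dm$X, dm$y, fixed = jj, max_iter = max_iter, tol = tol)
    lr <- 2 * (full$loglik_pen - red$loglik_pen)
    pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  structure(list(
    coefficients = data.frame(term = colnames(dm$X), estimate = full$beta,
                              se = full$se, p_value = pval, row.names = NULL),
    converged = full$converged, separation = NA, degenerate = FALSE,
    penalised = TRUE),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s)%s\n",
              if (x$penalised) "Firth-penalised" else "maximum likelihood",
              if (isTRUE(x$separation)) " [separation flagged]" else ""))
  if (x$degenerate) { cat("  degenerate data, no fit\n"); return(invisible(x)) }
  print(x$coefficients, digits = 4)
  invisible(x)
}

build_design_matrix <- function(records, terms) {
  if (length(terms))
    terms <- match.arg(terms, c("t", "z", "arm"), several.ok = TRUE)
  X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "beta0"))
  if ("t" %in% terms)
    X <- cbind(X, beta_t = records$block - 1)
  if ("z" %in% terms) {
    if (!is.null(attr(records, "z_observed")) &&
        !isTRUE(attr(records, "z_observed")))
      stop_domain("covariate z is flagged unobserved in this trial record")
    X <- cbind(X, beta_z = records$z)
  }
  if ("arm" %in% terms) {
    d <- attr(records, "design")
    K <- if (!is.null(d)) d$K else max(records$arm)
    A <- sapply(seq_len(K), function(k) as.numeric(records$arm == k))
    colnames(A) <- paste0("beta", seq_len(K))
    X <- cbind(X, A)
  }
  list(X = X, y = records$y,
       degenerate = all(records$y == 1) || all(records$y == 0))
}

glm_fit_degenerate <- function(dm, penalised) {
  structure(list(
    coefficients = data.frame(term = colnames(dm$X),
                              estimate = NA_real_, se = NA_real_,
                              p_value = NA_real_, row.names = NULL),
    converged = FALSE, separation = NA, degenerate = TRUE,
    penalised = penalised),
    class = "glm_fit")
}

# Newton--Raphson maximisation of the Jeffreys-penalised log-likelihood,
# optionally with one coefficient fixed at zero (for the penalised LRT).
# The modified score is U*_j = sum_i (y_i - mu_i + h_i (1/2 - mu_i)) x_ij,
# with h the diagonal of the weighted hat matrix.
firth_newton <- function(X, y, fixed = NULL, max_iter = 50, tol = 1e-6) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- rep(0, p)
  pen_ll <- function(beta) {
    mu <- clamp_prob(plogis(drop(X %*% beta)))
    info <- crossprod(X * (mu * (1 - mu)), X)
    ld <- determinant(info, logarithm = TRUE)
    sum(y * log(mu) + (1 - y) * log(1 - mu)) + 0.5 * as.numeric(ld$modulus)
  }
  ll <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- clamp_prob(plogis(drop(X %*% beta)))
    W <- mu * (1 - mu)
    info <- crossprod(X * W, X)
    inv <- try(solve(info), silent = TRUE)
    if (inherits(inv, "try-error")) break
    h <- rowSums((X %*% inv) * X) * W
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (length(free) == 0 || max(abs(score[free])) < tol) {
      converged <- TRUE
      break
    }
    step <- rep(0, p)
    step[free] <- drop(solve(info[free, free, drop = FALSE],
                             score[free]))
    # step halving on the penalised log-likelihood
    for (half in 0:12) {
      cand <- beta + step / 2^half
      cand[fixed] <- 0
      ll_new <- pen_ll(cand)
      if (ll_new >= ll - 1e-10) { beta <- cand; ll <- ll_new; break }
    }
  }
  mu <- clamp_prob(plogis(drop(X %*% beta)))
  info <- crossprod(X * (mu * (1 - mu)), X)
  inv <- try(solve(info), silent = TRUE)
  se <- if (inherits(inv, "try-error")) rep(NA_real_, p)
        else sqrt(pmax(diag(inv), 0))
  list(beta = beta, se = se, loglik_pen = ll, converged = converged)
}
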