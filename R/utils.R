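#' Logit and inverse-logit
#'
#' `logit(p)` is `log(p / (1 - p))`; `expit(u)` is its inverse
#' `exp(u) / (1 + exp(u))`.  Thin wrappers over [stats::qlogis()] /
#' [stats::plogis()], exported because success-rate calibrations throughout
#' the package are stated on the log-odds scale.
#'
#' @param p probability in (0, 1).
#' @param u log-odds.
#' @return a numeric vector.
#' @examples
#' logit(0.3)    # baseline log-odds for a 30% success rate
#' expit(0)      # 0.5
#' @export
logit <- function(p) qlogis(p)

#' @rdname logit
#' @export
expit <- function(u) plogis(u)

# clamp probabilities away from 0/1 before Bernoulli sampling so that
# downstream log-likelihoods stay finite
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Derive a replicate-level seed from a master seed
#'
#' Deterministic mixing of a master seed and a replicate index into a
#' 32-bit-safe integer seed.  Replicate `i` receives the same seed whatever
#' the total number of replicates, so scaled-down runs are prefix-consistent
#' with full runs.
#'
#' @param master master seed (integer).
#' @param i replicate index (integer, vectorised).
#' @return integer vector of seeds in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i) {
  m <- 2147483629  # largest prime below 2^31
  x <- (as.numeric(master) %% m) * 69069 + as.numeric(i) * 1234567 + 987
  x <- (x %% m) * 69069 + 12345
  as.integer(x %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_simplex <- function(p, tol = 1e-9, what = "allocation probabilities") {
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol) ||
      abs(sum(p) - 1) > tol) {
    stop_domain(what, " must lie on the probability simplex (got sum ",
                format(sum(p)), ")")
  }
  invisible(TRUE)
}
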