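#' Gittins index of a Bernoulli arm
#'
#' The Gittins index \eqn{\nu(s, f)} of a Bernoulli arm with a Beta(`s`,
#' `f`) posterior and discount factor `d` is the retirement rate
#' \eqn{\lambda} at which continuing the arm and retiring on a known arm of
#' rate \eqn{\lambda} have equal expected discounted reward.  It is computed
#' by bisection on \eqn{\lambda}, evaluating the continuation value by
#' backward induction over the triangular lattice of posterior states
#' truncated at `horizon` pulls.  Greedy play by Gittins index is the
#' optimal policy for the classic discounted multi-armed bandit.
#'
#' At `d = 0` the index reduces to the posterior mean `s / (s + f)`.
#'
#' @param s,f success / failure pseudo-counts (positive; the state after no
#'   data under a uniform prior is `(1, 1)`).
#' @param discount discount factor `d` in `[0, 1)`.
#' @param horizon truncation depth of the backward induction; defaults to
#'   the smallest `N` with `d^N < 1e-4` (1 for `d = 0`).
#' @param tol bisection tolerance on \eqn{\lambda}.
#' @return the index, a value in `[0, 1]`.
#' @examples
#' gittins_index(1, 1, discount = 0)    # 0.5, the posterior mean
#' @export
gittins_index <- function(s, f, discount = 0.995, horizon = NULL,
                          tol = 1e-4) {
  horizon <- horizon %||% default_horizon(discount)
  cpp_gittins_index(s, f, discount, as.integer(horizon), tol)
}

default_horizon <- function(discount, trunc_tol = 1e-4) {
  if (discount <= 0) return(1L)
  as.integer(max(1, ceiling(log(trunc_tol) / log(discount))))
}

#' Precompute a Gittins index table
#'
#' Computes \eqn{\nu(s, f)} for every integer state with
#' `s + f <= max_depth + prior_mass`, so that a trial of `max_depth`
#' patients never leaves the table.  The whole lattice is solved jointly:
#' one backward induction per calibration value \eqn{\lambda} yields the
#' continue/retire decision at every state simultaneously, and each state's
#' index is the midpoint of the grid interval where its decision flips
#' (grid resolution `2 * tol`).
#'
#' @param max_depth maximum number of observations an arm may accumulate.
#' @param discount discount factor in `[0, 1)`.
#' @param horizon induction truncation depth (default as in
#'   [gittins_index()]).
#' @param tol accuracy of the tabulated indices.
#' @param prior_mass pseudo-count mass of the prior (2 for Beta(1, 1)).
#' @return an object of class `gi_table`: the value matrix (entry `[s, f]`
#'   at row `s`, column `f`) plus the parameters used.
#' @seealso [gi_table_default()] for a session-memoised table.
#' @export
build_gi_table <- function(max_depth, discount = 0.995, horizon = NULL,
                           tol = 1e-3, prior_mass = 2) {
  if (max_depth < 2) stop_domain("max_depth must be >= 2")
  horizon <- horizon %||% default_horizon(discount)
  smax <- as.integer(max_depth + prior_mass)
  values <- cpp_build_gi_table(smax, discount, as.integer(horizon), tol)
  structure(list(values = values, discount = discount,
                 horizon = as.integer(horizon), tol = tol,
                 max_depth = as.integer(max_depth), smax = smax),
            class = "gi_table")
}

#' @export
print.gi_table <- function(x, ...) {
  cat(sprintf("Gittins table: discount %g, states s+f <= %d, horizon %d, tol %g\n",
              x$discount, x$smax, x$horizon, x$tol))
  invisible(x)
}

#' Look up tabulated indices
#'
#' @param table a `gi_table`.
#' @param s,f pseudo-counts (vectorised).
#' @return the tabulated index values.
#' @export
gi_lookup <- function(table, s, f) {
  # pseudo-count (s, f) is stored at matrix position [s + 1, f + 1]
  if (any(s < 1) || any(f < 1) || any(s + f > table$smax))
    stop_domain("Gittins table too shallow for state(s) requested")
  v <- table$values[cbind(s + 1, f + 1)]
  if (any(is.na(v)))
    stop_domain("Gittins table too shallow for state(s) requested")
  v
}

#' Session-memoised default Gittins table
#'
#' Building a deep table takes a few seconds; this getter caches tables per
#' `(discount, max_depth, tol)` within the R session.
#'
#' @inheritParams build_gi_table
#' @return a `gi_table`.
#' @export
gi_table_default <- function(max_depth, discount = 0.995, tol = 1e-3) {
  key <- paste("gi", discount, max_depth, tol, sep = "_")
  tab <- .driftrar_env[[key]]
  if (is.null(tab)) {
    tab <- build_gi_table(max_depth, discount = discount, tol = tol)
    assign(key, tab, envir = .driftrar_env)
  }
  tab
}

#' Serialise a Gittins table to JSON
#'
#' Values are written with 17 significant digits so a round-trip reproduces
#' the table bit-exactly.
#'
#' @param table a `gi_table`.
#' @param path output / input file path.
#' @return `write_gi_table()`: `path`, invisibly; `read_gi_table()`: the
#'   `gi_table`.
#' @export
write_gi_table <- function(table, path) {
  idx <- which(!is.na(table$values), arr.ind = TRUE)
  obj <- list(discount = table$discount, horizon = table$horizon,
              tol = table$tol, max_depth = table$max_depth,
              smax = table$smax,
              entries = data.frame(s = idx[, 1] - 1L, f = idx[, 2] - 1L,
                                   value = table$values[idx]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_gi_table
#' @export
read_gi_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  values <- matrix(NA_real_, obj$smax + 1, obj$smax + 1)
  values[cbind(obj$entries$s + 1, obj$entries$f + 1)] <- obj$entries$value
  structure(list(values = values, discount = obj$discount,
                 horizon = as.integer(obj$horizon), tol = obj$tol,
                 max_depth = as.integer(obj$max_depth),
                 smax = as.integer(obj$smax)),
            class = "gi_table")
}

#' Structural checks on a Gittins table
#'
#' Verifies, up to the table's accuracy `tol`, that every entry lies in
#' `[0, 1]`, dominates the posterior mean (for positive discount),
#' increases in `s` at fixed `f`, decreases in `f` at fixed `s`, and
#' satisfies the exchange ordering `nu(s+1, f) > nu(s, f+1)`.
#'
#' @param table a `gi_table`.
#' @return `TRUE` invisibly; errors with a message naming the violated
#'   property otherwise.
#' @export
check_gi_table <- function(table) {
  v <- table$values
  tol <- 2 * table$tol
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1)) stop_domain("index outside [0, 1]")
  smax <- table$smax
  mean_mat <- outer(0:smax, 0:smax, function(s, f) s / pmax(s + f, 1))
  if (table$discount > 0 && any(v[ok] < mean_mat[ok] - tol))
    stop_domain("index below posterior mean")
  at <- function(s, f) v[cbind(s + 1, f + 1)]  # pseudo-counts -> positions
  for (s in 1:(smax - 2)) {
    f <- 1:(smax - s - 1)
    if (any(at(s + 1, f) - at(s, f) < -tol, na.rm = TRUE))
      stop_domain("index not increasing in s at fixed f")
    if (any(at(s, f + 1) - at(s, f) > tol, na.rm = TRUE))
      stop_domain("index not decreasing in f at fixed s")
    if (any(at(s + 1, f) - at(s, f + 1) < -tol, na.rm = TRUE))
      stop_domain("exchange ordering nu(s+1,f) > nu(s,f+1) violated")
  }
  invisible(TRUE)
}
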