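#' Sample one block of patients
#'
#' Draws `b` patients for block `j`: each is allocated to an arm with the
#' supplied probabilities, receives a covariate `Z ~ Bern(q_j)`, and a
#' binary outcome from the logistic outcome model.  Uses the current R
#' random stream.
#'
#' @param j block index.
#' @param probs allocation probabilities over arms `0..K` (must sum to 1).
#' @param scenario a [scenario_spec()].
#' @return a data frame with columns `block`, `patient_in_block`, `arm`,
#'   `z`, `y`.
#' @export
sample_block <- function(j, probs, scenario) {
  d <- scenario$design
  assert_simplex(probs)
  arms <- sample.int(d$K + 1, d$b, replace = TRUE, prob = probs) - 1L
  z <- rbinom(d$b, 1, scenario$q_path$q[j])
  p <- clamp_prob(success_probability(rep(j, d$b), z, arms, scenario$params,
                                      J = d$J))
  y <- rbinom(d$b, 1, p)
  data.frame(block = j, patient_in_block = seq_len(d$b),
             arm = arms, z = z, y = y)
}

#' Posterior counts per arm
#'
#' The sufficient statistics every allocation rule works from: per arm,
#' prior-inclusive success and failure pseudo-counts (`s`, `f`) and the
#' number of patients allocated so far (`n`).
#'
#' @param design a [design_spec()].
#' @return an object of class `posterior_counts` (lists `s`, `f`, `n`,
#'   indexed by arm `0..K`).
#' @export
posterior_counts <- function(design) {
  n <- design$K + 1L
  structure(list(s = rep(design$prior_a, n), f = rep(design$prior_b, n),
                 n = rep(0L, n)), class = "posterior_counts")
}

#' @param counts a `posterior_counts` object.
#' @param arms,y integer vectors of allocated arms (0-based) and outcomes.
#' @rdname posterior_counts
#' @export
update_counts <- function(counts, arms, y) {
  for (k in seq_along(counts$s)) {
    on_k <- arms == (k - 1L)
    counts$s[k] <- counts$s[k] + sum(y[on_k])
    counts$f[k] <- counts$f[k] + sum(on_k) - sum(y[on_k])
    counts$n[k] <- counts$n[k] + sum(on_k)
  }
  counts
}

#' Simulate one complete trial
#'
#' Runs a block-randomised trial under an allocation policy: block 1 is
#' allocated uniformly; before each later block the policy maps the
#' accumulated data (blocks `1..j-1` only) to allocation probabilities.
#'
#' @param policy a [make_policy()] object.
#' @param scenario a [scenario_spec()] with the same design.
#' @param seed optional integer seed (sets the R random stream).
#' @return a `trial_record`: a data frame of per-patient rows (`block`,
#'   `patient_in_block`, `arm`, `z`, `y`) with attributes `probs` (the
#'   `J x (K+1)` matrix of per-block allocation probabilities), `design`,
#'   `scenario_label` and `seed`.
#' @export
run_trial <- function(policy, scenario, seed = NULL) {
  d <- scenario$design
  if (!identical(unclass(policy$design)[c("K", "T_total", "J", "b")],
                 unclass(d)[c("K", "T_total", "J", "b")]))
    stop_domain("policy and scenario were built for different designs")
  if (!is.null(seed)) set.seed(seed)
  counts <- posterior_counts(d)
  probs_mat <- matrix(NA_real_, d$J, d$K + 1)
  blocks <- vector("list", d$J)
  for (j in seq_len(d$J)) {
    probs <- if (j == 1) rep(1 / (d$K + 1), d$K + 1) else policy$probs(j, counts)
    probs_mat[j, ] <- probs
    blk <- sample_block(j, probs, scenario)
    counts <- update_counts(counts, blk$arm, blk$y)
    blocks[[j]] <- blk
  }
  rec <- do.call(rbind, blocks)
  attr(rec, "probs") <- probs_mat
  attr(rec, "design") <- d
  attr(rec, "scenario_label") <- scenario$label
  attr(rec, "z_observed") <- scenario$z_observed
  attr(rec, "seed") <- seed %||% NA_integer_
  class(rec) <- c("trial_record", "data.frame")
  rec
}

#' Patient-benefit summaries of a trial
#'
#' `p_star()` is the fraction of trial patients allocated to the (declared)
#' best arm; `total_successes()` the number of in-trial successes.
#'
#' @param record a `trial_record`.
#' @param best index of the truly best arm.
#' @return a scalar.
#' @export
p_star <- function(record, best) mean(record$arm == best)

#' @rdname p_star
#' @export
total_successes <- function(record) sum(record$y)

#' Read and write trial records
#'
#' A `trial_record` serialises to a per-patient CSV plus a JSON sidecar
#' (same path with extension `.json`) holding the per-block allocation
#' probabilities, the design, and the seed.
#'
#' @param record a `trial_record`.
#' @param path CSV file path.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   returns a `trial_record`.
#' @export
write_trial_csv <- function(record, path) {
  write.csv(as.data.frame(record), path, row.names = FALSE)
  d <- attr(record, "design")
  side <- list(probs = unname(apply(attr(record, "probs"), 1, as.numeric,
                                    simplify = FALSE)),
               design = unclass(d),
               scenario_label = attr(record, "scenario_label") %||% "custom",
               z_observed = isTRUE(attr(record, "z_observed")),
               seed = attr(record, "seed"))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  rec <- read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- do.call(design_spec, side$design[c("K", "T_total", "J", "b",
                                          "prior_a", "prior_b")])
  attr(rec, "probs") <- matrix(unlist(side$probs), nrow = d$J, byrow = TRUE)
  attr(rec, "design") <- d
  attr(rec, "scenario_label") <- side$scenario_label
  attr(rec, "z_observed") <- isTRUE(side$z_observed)
  attr(rec, "seed") <- side$seed
  class(rec) <- c("trial_record", "data.frame")
  rec
}
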