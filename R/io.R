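#' Load a simulation configuration file
#'
#' Parses a YAML configuration into a validated bundle of scenario, policy
#' configuration and simulation settings.  Recognised keys:
#'
#' ```yaml
#' design: {K: 1, T: 100, J: 5, b: 20, prior_a: 1, prior_b: 1}
#' params: {beta0: -0.8473, beta_t: 0, beta_z: 0, beta_k: [0],
#'          effect_mode: logit_additive}
#' q_path: [0.5, 0.55, 0.6, 0.65, 0.7]   # or {start: 0.5, step: 0.05}
#' D: 0.24          # optional; solves beta_t from the overall drift
#' policy: {rule: FLGI, flgi_mc_reps: 100, ts_mc_draws: 10000, gamma: 2,
#'          gi_table: table.json}
#' sim: {n_rep: 500, test: rand, M: 200, alpha: 0.05, n_cal: 2000}
#' seed: 1
#' ```
#'
#' Unspecified model parameters default to a 30% baseline success rate with
#' no trend, no covariate effect, and null arm effects.  Validation errors
#' name the offending key.
#'
#' @param path path to the YAML file.
#' @return a list with elements `scenario`, `policy_config`,
#'   `gi_table_path`, `sim`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  des <- cfg$design
  for (key in c("K", "T", "J", "b"))
    if (is.null(des[[key]])) stop_domain("design.", key, " is required")
  design <- tryCatch(
    design_spec(des$K, des$T, des$J, des$b,
                prior_a = des$prior_a %||% 1, prior_b = des$prior_b %||% 1),
    error = function(e) stop_domain("design: ", conditionMessage(e)))
  par <- cfg$params %||% list()
  beta_k <- as.numeric(par$beta_k %||% rep(0, design$K))
  if (length(beta_k) != design$K)
    stop_domain("params.beta_k must have length K = ", design$K)
  params <- model_params(
    beta0 = par$beta0 %||% logit(0.3),
    beta_t = par$beta_t %||% 0,
    beta_z = par$beta_z %||% 0,
    beta_k = beta_k,
    effect_mode = par$effect_mode %||% "logit_additive")
  qp <- cfg$q_path
  q_path <- if (is.null(qp)) {
    covariate_path(rep(0, design$J))
  } else if (is.list(qp) && !is.null(qp$start)) {
    linear_q_path(qp$start, qp$step %||% 0, design$J)
  } else {
    if (length(unlist(qp)) != design$J)
      stop_domain("q_path must have length J = ", design$J)
    covariate_path(unlist(qp))
  }
  scenario <- scenario_spec(design, params, q_path = q_path, D = cfg$D,
                            z_observed = isTRUE(cfg$z_observed))
  pol <- cfg$policy %||% list(rule = "CR")
  if (is.null(pol$rule) ||
      !pol$rule %in% c("CR", "TS", "RSIHR", "FLGI", "CFLGI"))
    stop_domain("policy.rule must be one of CR, TS, RSIHR, FLGI, CFLGI")
  pconf <- policy_config(pol$rule,
                         ts_mc_draws = pol$ts_mc_draws %||% 1e4,
                         flgi_mc_reps = pol$flgi_mc_reps %||% 100,
                         gamma = pol$gamma %||% 2,
                         rsihr_form = pol$rsihr_form %||% "sqrt")
  sim <- cfg$sim %||% list()
  list(scenario = scenario, policy_config = pconf,
       gi_table_path = pol$gi_table,
       sim = list(n_rep = sim$n_rep %||% 100L,
                  test = sim$test %||% "none",
                  M = sim$M %||% 500L,
                  alpha = sim$alpha %||% 0.05,
                  n_cal = sim$n_cal %||% 2000L),
       seed = cfg$seed %||% 1L)
}

#' Write simulation results with a reproducibility manifest
#'
#' Emits `summary.json` (the aggregated operating characteristics plus a
#' config echo) and, when per-replicate data are attached,
#' `replicates.csv`, then returns a manifest listing every file written
#' with its MD5 checksum and the master seed — enough to re-run
#' bit-identically.
#'
#' @param summary an `op_chars` object from [operating_characteristics()].
#' @param out_dir output directory (created if missing).
#' @param config_echo optional configuration list echoed into the summary.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
write_results <- function(summary, out_dir, config_echo = NULL) {
  stopifnot(inherits(summary, "op_chars"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  sm <- unclass(summary)
  sm$replicates <- NULL
  sm$coef_raw <- NULL
  sm$config <- config_echo
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(sm, sum_path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  files <- c(files, sum_path)
  if (!is.null(summary$replicates)) {
    rep_path <- file.path(out_dir, "replicates.csv")
    write.csv(summary$replicates, rep_path, row.names = FALSE)
    files <- c(files, rep_path)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("driftrar")),
    seed = summary$seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(manifest)
}
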