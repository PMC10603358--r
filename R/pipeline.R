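#' Assemble a pipeline run configuration
#'
#' A run configuration ties the pipeline stages together: the cohort source
#' (a path to a cohort CSV or a [cohort_spec()]), the plasmode design, the
#' model list, TMLE options, sensitivity options, the output directory, and
#' a single global seed that fans out deterministically to every stage (see
#' [derive_seed()]).
#'
#' @param cohort a file path or a [cohort_spec()].
#' @param design a [plasmode_design()] or `NULL` (built by [auto_design()]
#'   at run time).
#' @param models integer subset of 1..8.
#' @param control a [ps_control()].
#' @param gap_grid sensitivity gap grid (risk-difference units).
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(cohort, design = NULL, models = 1:8,
                       control = ps_control(),
                       gap_grid = seq(-0.05, 0.05, by = 0.005),
                       out_dir = "results", seed = 1L) {
  stopifnot(length(models) >= 1, all(models %in% 1:8))
  if (is.character(cohort) && !file.exists(cohort)) {
    stop("cohort file does not exist: ", cohort)
  }
  structure(list(cohort = cohort, design = design, models = as.integer(models),
                 control = control, gap_grid = gap_grid, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized fields: `cohort` (path or a `cohort_spec` mapping passed to
#' [cohort_spec()]), `design` (mapping passed to [plasmode_design()]),
#' `models`, `control` (mapping passed to [ps_control()]), `gap_grid`,
#' `out_dir`, `seed` (mandatory).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) stop("config must set a seed")
  cohort <- raw$cohort
  if (is.list(cohort)) cohort <- do.call(cohort_spec, cohort)
  design <- raw$design
  if (is.list(design)) {
    design$treatment_coefficients <- unlist(design$treatment_coefficients)
    design$outcome_coefficients <- unlist(design$outcome_coefficients)
    design <- do.call(plasmode_design, design)
  }
  run_config(
    cohort = cohort, design = design,
    models = raw$models %||% 1:8,
    control = if (is.list(raw$control)) do.call(ps_control, raw$control) else ps_control(),
    gap_grid = raw$gap_grid %||% seq(-0.05, 0.05, by = 0.005),
    out_dir = raw$out_dir %||% "results",
    seed = raw$seed
  )
}

.load_cohort <- function(config) {
  if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else if (inherits(config$cohort, "cohort_data")) {
    config$cohort
  } else {
    read_cohort_csv(config$cohort)
  }
}

.write_manifest <- function(config, stage, extra, path) {
  manifest <- c(list(
    stage = stage,
    seed = config$seed,
    models = config$models,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("blindps"))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate (or load) the cohort and write it with a summary
#'
#' @param config a `run_config`.
#' @return invisibly, the screened [cohort_data()]; writes `cohort.csv`,
#'   `cohort_summary.csv`, and a manifest under `config$out_dir`.
#' @export
run_make_cohort <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- .load_cohort(config)
  cohort <- screen_prevalence(cohort)
  write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
  smry <- cohort_summary(cohort)
  data.table::fwrite(smry, file.path(config$out_dir, "cohort_summary.csv"))
  .write_manifest(config, "make-cohort",
                  list(n = length(cohort$A), p = ncol(cohort$W)),
                  file.path(config$out_dir, "make_cohort_manifest.json"))
  invisible(cohort)
}

#' Run the outcome-blind simulation loop and model comparison
#'
#' Generates plasmode replicates from the cohort covariates, runs each
#' requested model's propensity-score + TMLE pipeline on every replicate,
#' and writes the metrics table, per-replicate estimates, and a manifest.
#'
#' @param config a `run_config` with a `design` (or `NULL` to use
#'   [auto_design()] defaults).
#' @return invisibly, the [compare_models()] result.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- .load_cohort(config)
  design <- config$design %||%
    auto_design(cohort, seed = derive_seed(config$seed, "design"))
  reps <- run_replicates(cohort, design)
  truth <- true_effect(design, cohort$W)
  cmp <- compare_models(reps, truth$psi_true, config$models,
                        control = config$control,
                        seed = derive_seed(config$seed, "compare"))
  data.table::fwrite(cmp$metrics, file.path(config$out_dir, "sim_metrics.csv"))
  data.table::fwrite(cmp$estimates, file.path(config$out_dir, "sim_estimates.csv"))
  .write_manifest(config, "simulate",
                  list(psi_true = truth$psi_true,
                       n_replicates = design$n_replicates,
                       n_per_replicate = design$n_per_replicate,
                       selected_model = cmp$selected),
                  file.path(config$out_dir, "simulate_manifest.json"))
  invisible(cmp)
}

#' Estimate the risk difference on the cohort with a chosen model
#'
#' Complete-case TMLE with the requested propensity-score model (first
#' entry of `config$models`), alongside the unadjusted risk difference.
#' Writes the result JSON and a manifest.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with `tmle` and `unadjusted` results.
#' @export
run_estimate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- complete_case(.load_cohort(config))
  m <- config$models[1]
  g <- fit_ps(cohort, m, config$control, derive_seed(config$seed, "estimate"))
  res <- estimate_ate(cohort, g, control = config$control,
                      seed = derive_seed(config$seed, "estimate_q"))
  unadj <- unadjusted_rd(cohort)
  out <- lapply(list(tmle = res, unadjusted = unadj), function(r) {
    list(model_id = r$model_id, psi_hat = r$psi_hat, se = r$standard_error,
         ci = c(r$ci_lower, r$ci_upper), epsilon = r$epsilon,
         eif_mean = r$eif_mean, n_used = r$n_used)
  })
  jsonlite::write_json(out, file.path(config$out_dir, "estimate.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(config, "estimate", list(model_id = m),
                  file.path(config$out_dir, "estimate_manifest.json"))
  invisible(list(tmle = res, unadjusted = unadj))
}

#' Causal-gap sensitivity analysis for an estimation result
#'
#' @param config a `run_config`.
#' @param result a `tmle_result`; when `NULL`, [run_estimate()] is invoked.
#' @param unadjusted optional `tmle_result`-shaped unadjusted summary used
#'   for the adjustment-unit denominator.
#' @param sd_outcome optional outcome-scale SD for effect-size units.
#' @return invisibly, the [sensitivity_curve()]; writes the tidy curve CSV
#'   and a manifest carrying the G-value.
#' @export
run_sensitivity <- function(config, result = NULL, unadjusted = NULL,
                            sd_outcome = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(result)) {
    est <- run_estimate(config)
    result <- est$tmle
    unadjusted <- est$unadjusted
  }
  adj <- if (!is.null(unadjusted)) abs(unadjusted$psi_hat - result$psi_hat)
  curve <- sensitivity_curve(result, config$gap_grid,
                             sd_outcome = sd_outcome, adj_magnitude = adj)
  data.table::fwrite(curve$curve, file.path(config$out_dir, "sensitivity_curve.csv"))
  .write_manifest(config, "sensitivity", list(g_value = curve$g_value),
                  file.path(config$out_dir, "sensitivity_manifest.json"))
  invisible(curve)
}
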