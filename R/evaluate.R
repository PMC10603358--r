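#' Simulation performance metrics
#'
#' Bias, mean squared error, and 95% confidence-interval coverage of a set
#' of estimates against the known true effect of a plasmode design.
#' Intervals are treated as closed: a truth equal to a bound counts as
#' covered.
#'
#' @param estimates numeric vector of point estimates.
#' @param psi_true the true risk difference.
#' @return `bias`: `mean(estimates) - psi_true`; `mse`: mean squared
#'   deviation from `psi_true`.
#' @export
bias <- function(estimates, psi_true) {
  if (length(estimates) == 0) stop("no estimates")
  mean(estimates) - psi_true
}

#' @rdname bias
#' @export
mse <- function(estimates, psi_true) {
  if (length(estimates) == 0) stop("no estimates")
  mean((estimates - psi_true)^2)
}

#' @rdname bias
#' @param ci_lower,ci_upper numeric vectors of interval bounds.
#' @export
coverage <- function(ci_lower, ci_upper, psi_true) {
  if (length(ci_lower) == 0) stop("no intervals")
  stopifnot(length(ci_lower) == length(ci_upper))
  mean(ci_lower <= psi_true & psi_true <= ci_upper)
}

# ranking rule: primary |bias|, ties by MSE, then lower model id
.rank_models <- function(metrics) {
  ok <- metrics[!metrics$excluded, , drop = FALSE]
  if (nrow(ok) == 0) stop("every model was excluded; nothing to rank")
  ok <- ok[order(abs(ok$bias), ok$mse, ok$model_id), , drop = FALSE]
  ok$model_id[1]
}

#' Compare propensity-score models across plasmode replicates
#'
#' Runs the full propensity-score + TMLE pipeline for each requested model
#' on each replicate, and summarizes per-model bias, MSE, and coverage
#' against the design's true effect. Models are ranked primarily by
#' absolute bias with ties broken by MSE; a model failing on more than
#' `fail_tolerance` of replicates is flagged and excluded from ranking.
#'
#' @param replicates list of `plasmode_replicate` objects (see
#'   [run_replicates()]).
#' @param psi_true true risk difference (see [true_effect()]).
#' @param model_ids subset of 1..8.
#' @param control a [ps_control()].
#' @param seed integer seed; per-replicate fits use seeds derived from it.
#' @param fail_tolerance maximum tolerated failure proportion per model.
#' @return a list: `metrics` (one row per model: bias, mse, coverage,
#'   n_replicates, mc_se_bias, excluded), `selected` (best model id), and
#'   `estimates` (long per-replicate results).
#' @export
compare_models <- function(replicates, psi_true, model_ids = 1:8,
                           control = ps_control(), seed = 1L,
                           fail_tolerance = 0.1) {
  stopifnot(length(replicates) >= 2, all(model_ids %in% 1:8))
  rows <- list()
  # the initial outcome regression does not depend on the PS model: fit it
  # once per replicate and share it across models (and as q_init for the
  # collaborative learners; cross-fitted learners refit within folds)
  q_cache <- lapply(seq_along(replicates), function(r) {
    fit_initial_outcome(replicates[[r]]$data, control,
                        seed = derive_seed(seed, "q_init", r))
  })
  for (m in model_ids) {
    for (r in seq_along(replicates)) {
      dat <- replicates[[r]]$data
      fit_seed <- derive_seed(seed, sprintf("model%d", m), r)
      res <- tryCatch({
        g <- fit_ps(dat, m, control, fit_seed, q_init = q_cache[[r]])
        est <- estimate_ate(dat, g, q = q_cache[[r]], control = control,
                            seed = fit_seed)
        data.frame(model_id = m, replicate = r, psi_hat = est$psi_hat,
                   ci_lower = est$ci_lower, ci_upper = est$ci_upper,
                   failed = FALSE, message = "")
      }, error = function(e) {
        data.frame(model_id = m, replicate = r, psi_hat = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   failed = TRUE, message = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  est <- do.call(rbind, rows)
  metrics <- do.call(rbind, lapply(model_ids, function(m) {
    em <- est[est$model_id == m & !est$failed, , drop = FALSE]
    fail_rate <- 1 - nrow(em) / sum(est$model_id == m)
    excluded <- fail_rate > fail_tolerance
    if (excluded) {
      msgs <- unique(est$message[est$model_id == m & est$failed])
      warning(sprintf("Model %d failed on %.0f%% of replicates (%s); excluded from ranking",
                      m, 100 * fail_rate, paste(msgs, collapse = "; ")))
    }
    data.frame(
      model_id = m,
      bias = if (nrow(em)) bias(em$psi_hat, psi_true) else NA_real_,
      mse = if (nrow(em)) mse(em$psi_hat, psi_true) else NA_real_,
      coverage = if (nrow(em)) coverage(em$ci_lower, em$ci_upper, psi_true) else NA_real_,
      n_replicates = nrow(em),
      mc_se_bias = if (nrow(em) > 1) stats::sd(em$psi_hat) / sqrt(nrow(em)) else NA_real_,
      excluded = excluded
    )
  }))
  list(metrics = metrics, selected = .rank_models(metrics), estimates = est)
}
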