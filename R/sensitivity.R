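#' G-value: minimal causal gap negating the study finding
#'
#' The causal gap is the discrepancy between the statistical estimand and
#' the causal parameter induced by violated identification assumptions; an
#' additive gap shifts the estimate and both confidence bounds together.
#' The G-value is the smallest gap magnitude whose shift flips the
#' interval's classification against the null (from containing 0 to
#' excluding it, or vice versa). In closed form this is
#' `min(|ci_lower|, |ci_upper|)`, and 0 when a bound already sits on the
#' null.
#'
#' @param ci_lower,ci_upper bounds of the 95% confidence interval on the
#'   risk-difference scale.
#' @return the G-value (nonnegative scalar, risk-difference units).
#' @export
g_value <- function(ci_lower, ci_upper) {
  stopifnot(ci_lower <= ci_upper)
  min(abs(ci_lower), abs(ci_upper))
}

#' Causal-gap sensitivity curve
#'
#' Shifts the point estimate and 95% confidence bounds additively over a
#' grid of causal-gap values, reporting each gap also in effect-size units
#' (gap divided by the outcome-scale standard deviation, for a binary
#' outcome `sqrt(p*(1-p))`) and in adjustment units (gap divided by the
#' magnitude of the bias adjustment due to measured confounders, i.e.
#' `|unadjusted - adjusted|`). Unit columns are `NA` when the corresponding
#' denominator is not supplied or not positive.
#'
#' @param result a `tmle_result` (see [estimate_ate()]).
#' @param gap_grid numeric vector of gap values (risk-difference units).
#' @param sd_outcome outcome-scale standard deviation, or `NULL`.
#' @param adj_magnitude `|unadjusted - adjusted|` point-estimate distance,
#'   or `NULL`.
#' @return a list of class `sensitivity_curve`: `curve` (data.frame with
#'   columns gap, estimate, lower, upper, delta_units, adj_units) and
#'   `g_value`.
#' @export
sensitivity_curve <- function(result, gap_grid, sd_outcome = NULL,
                              adj_magnitude = NULL) {
  stopifnot(inherits(result, "tmle_result"), length(gap_grid) >= 1)
  curve <- data.frame(
    gap = gap_grid,
    estimate = result$psi_hat + gap_grid,
    lower = result$ci_lower + gap_grid,
    upper = result$ci_upper + gap_grid,
    delta_units = if (!is.null(sd_outcome) && sd_outcome > 0) {
      gap_grid / sd_outcome
    } else NA_real_,
    adj_units = if (!is.null(adj_magnitude) && adj_magnitude > 0) {
      gap_grid / adj_magnitude
    } else NA_real_
  )
  structure(list(curve = curve,
                 g_value = g_value(result$ci_lower, result$ci_upper)),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> %d gap values | G-value %.4g\n",
              nrow(x$curve), x$g_value))
  invisible(x)
}
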