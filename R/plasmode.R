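#' Specify an outcome-blind (plasmode) simulation design
#'
#' A plasmode design bootstraps covariate rows from an observed cohort —
#' preserving the joint covariate structure — and injects known logistic
#' treatment and outcome mechanisms, so the true causal risk difference is
#' known while the analyst never touches the source cohort's real treatment
#' or outcome. Intercepts are calibrated once against the source covariate
#' pool so the marginal design is fixed across replicates.
#'
#' @param treatment_coefficients named numeric vector: column -> log-odds
#'   coefficient in the treatment model.
#' @param outcome_coefficients named numeric vector: column -> log-odds
#'   coefficient in the outcome model (shared by both potential outcomes).
#' @param treatment_effect log-odds effect of treatment on the outcome
#'   (the injected causal signal; 0 gives a sharp null).
#' @param treatment_intercept_target,outcome_intercept_target marginal
#'   `P(A = 1)` and `P(Y = 1)` targets in (0, 1).
#' @param n_per_replicate,n_replicates replicate size and count.
#' @param seed integer; replicate seeds are derived deterministically.
#' @return an object of class `plasmode_design`.
#' @export
plasmode_design <- function(treatment_coefficients,
                            outcome_coefficients,
                            treatment_effect,
                            treatment_intercept_target = 0.364,
                            outcome_intercept_target = 0.042,
                            n_per_replicate = 2000L,
                            n_replicates = 100L,
                            seed = 1L) {
  stopifnot(
    is.numeric(treatment_coefficients), !is.null(names(treatment_coefficients)) ||
      length(treatment_coefficients) == 0,
    is.numeric(outcome_coefficients), !is.null(names(outcome_coefficients)) ||
      length(outcome_coefficients) == 0,
    treatment_intercept_target > 0, treatment_intercept_target < 1,
    outcome_intercept_target > 0, outcome_intercept_target < 1,
    n_per_replicate >= 1, n_replicates >= 0
  )
  structure(list(
    treatment_coefficients = treatment_coefficients,
    outcome_coefficients = outcome_coefficients,
    treatment_effect = treatment_effect,
    treatment_intercept_target = treatment_intercept_target,
    outcome_intercept_target = outcome_intercept_target,
    n_per_replicate = as.integer(n_per_replicate),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    alpha_A = NULL, alpha_Y = NULL
  ), class = "plasmode_design")
}

#' Convenience constructor: design over the most prevalent binary covariates
#'
#' Selects the `k_treatment + k_outcome - k_shared` most prevalent binary
#' covariates of the source, assigns the first `k_treatment` to the
#' treatment model and the last `k_outcome` to the outcome model (the
#' overlap of size `k_shared` confounds), with alternating-sign
#' coefficients of the given magnitudes.
#'
#' @param source a [cohort_data()] (only its `W` is used).
#' @param k_treatment,k_outcome,k_shared numbers of treatment-model,
#'   outcome-model, and shared (confounding) covariates.
#' @param coef_treatment,coef_outcome coefficient magnitudes (log-odds).
#' @param treatment_effect injected log-odds treatment effect.
#' @param ... passed to [plasmode_design()].
#' @return a `plasmode_design`.
#' @export
auto_design <- function(source, k_treatment = 4L, k_outcome = 4L,
                        k_shared = 2L, coef_treatment = 0.5,
                        coef_outcome = 0.7, treatment_effect = 0.4, ...) {
  stopifnot(inherits(source, "cohort_data"),
            k_shared <= k_treatment, k_shared <= k_outcome)
  W <- source$W
  bin <- vapply(seq_len(ncol(W)), function(j) is_binary_col(W[, j]), logical(1))
  prev <- colMeans(W)
  prev[!bin] <- -Inf
  k_tot <- k_treatment + k_outcome - k_shared
  if (sum(bin) < k_tot) stop("not enough binary covariates for auto_design")
  cols <- colnames(W)[order(prev, decreasing = TRUE)][seq_len(k_tot)]
  tc <- stats::setNames(coef_treatment * rep_len(c(1, -1), k_treatment),
                        cols[seq_len(k_treatment)])
  oc <- stats::setNames(coef_outcome * rep_len(c(1, -1), k_outcome),
                        cols[seq(k_tot - k_outcome + 1, k_tot)])
  plasmode_design(tc, oc, treatment_effect = treatment_effect, ...)
}

.design_lp <- function(W, coefs) {
  if (length(coefs) == 0) return(rep(0, nrow(W)))
  missing_cols <- setdiff(names(coefs), colnames(W))
  if (length(missing_cols) > 0) {
    stop("design references absent columns: ", paste(missing_cols, collapse = ", "))
  }
  drop(W[, names(coefs), drop = FALSE] %*% coefs)
}

#' Calibrate a plasmode design against a covariate pool
#'
#' Fixes the treatment intercept so the pool-average treatment probability
#' hits its target, then the outcome intercept so the pool-average marginal
#' outcome rate (mixing the two potential-outcome probabilities by the
#' calibrated treatment probabilities) hits its target.
#'
#' @param design a `plasmode_design`.
#' @param W_pool covariate matrix (the bootstrap source pool).
#' @return the design with `alpha_A`, `alpha_Y` filled in.
#' @export
calibrate_design <- function(design, W_pool) {
  stopifnot(inherits(design, "plasmode_design"))
  W_pool <- as.matrix(W_pool)
  lp_A <- .design_lp(W_pool, design$treatment_coefficients)
  design$alpha_A <- calibrate_intercept(lp_A, design$treatment_intercept_target,
                                        "treatment_intercept_target")
  g <- stats::plogis(design$alpha_A + lp_A)
  lp_Y <- .design_lp(W_pool, design$outcome_coefficients)
  bA <- design$treatment_effect
  f <- function(a) {
    mean(g * stats::plogis(a + bA + lp_Y) + (1 - g) * stats::plogis(a + lp_Y)) -
      design$outcome_intercept_target
  }
  m <- max(abs(lp_Y), abs(bA), 1)
  t0 <- stats::qlogis(design$outcome_intercept_target)
  design$alpha_Y <- tryCatch(
    stats::uniroot(f, c(t0 - m - 1, t0 + m + 1), extendInt = "upX", tol = 1e-12)$root,
    error = function(e) stop("calibration failure for target 'outcome_intercept_target': ",
                             conditionMessage(e))
  )
  design
}

#' Bootstrap covariate rows from a source cohort
#'
#' Samples whole rows of the source covariate matrix with replacement, so
#' within-subject covariate patterns are never recombined. Only `W` of the
#' source is read — the source treatment and outcome never enter the
#' simulation (the outcome-blindness contract).
#'
#' @param source a [cohort_data()] or covariate matrix.
#' @param n number of rows to draw.
#' @param seed integer seed.
#' @return an `n` x `p` covariate matrix.
#' @export
bootstrap_covariates <- function(source, n, seed) {
  W <- if (inherits(source, "cohort_data")) source$W else as.matrix(source)
  if (nrow(W) == 0) stop("empty source: no covariate rows to bootstrap")
  set.seed(seed)
  W[sample.int(nrow(W), n, replace = TRUE), , drop = FALSE]
}

#' Inject known treatment and outcome mechanisms into bootstrapped covariates
#'
#' Draws treatment from the calibrated logistic treatment model, both
#' potential outcomes from the calibrated outcome model (with and without
#' the treatment effect), and assembles the observed outcome by
#' consistency: `Y = A*Y1 + (1-A)*Y0`. Potential outcomes are coupled
#' through a shared uniform per subject.
#'
#' @param W_boot bootstrapped covariate matrix.
#' @param design a calibrated `plasmode_design` (see [calibrate_design()]);
#'   an uncalibrated design is calibrated against `W_boot`.
#' @param replicate_seed integer seed for this replicate.
#' @return an object of class `plasmode_replicate`: `data` (a
#'   [cohort_data()] with `C` all 1), `Y1`, `Y0`, `replicate_seed`.
#' @export
inject_mechanisms <- function(W_boot, design, replicate_seed) {
  stopifnot(inherits(design, "plasmode_design"))
  W_boot <- as.matrix(W_boot)
  if (is.null(design$alpha_A) || is.null(design$alpha_Y)) {
    design <- calibrate_design(design, W_boot)
  }
  n <- nrow(W_boot)
  set.seed(replicate_seed)
  gA <- stats::plogis(design$alpha_A + .design_lp(W_boot, design$treatment_coefficients))
  A <- as.integer(stats::runif(n) < gA)
  lp_Y <- design$alpha_Y + .design_lp(W_boot, design$outcome_coefficients)
  p1 <- stats::plogis(lp_Y + design$treatment_effect)
  p0 <- stats::plogis(lp_Y)
  u <- stats::runif(n)
  Y1 <- as.integer(u < p1)
  Y0 <- as.integer(u < p0)
  Y <- A * Y1 + (1L - A) * Y0
  structure(list(
    data = cohort_data(W_boot, A, Y, C = rep(1L, n)),
    Y1 = Y1, Y0 = Y0, replicate_seed = as.integer(replicate_seed)
  ), class = "plasmode_replicate")
}

#' True causal risk difference of a plasmode design
#'
#' The causal estimand of the simulated population: the mean over the
#' covariate pool of the difference between the two potential-outcome
#' probabilities. When `mc_draws` is at least the pool size (or `NULL`),
#' the mean is taken exactly over every pool row (the bootstrap
#' superpopulation is the pool itself) and the Monte Carlo standard error
#' is zero; otherwise a seeded subsample of rows is used.
#'
#' @param design a `plasmode_design`.
#' @param W_pool covariate matrix defining the population.
#' @param mc_draws number of pool rows to draw, or `NULL` for all.
#' @return a list of class `true_effect`: `psi_true`, `mc_standard_error`.
#' @export
true_effect <- function(design, W_pool, mc_draws = NULL) {
  stopifnot(inherits(design, "plasmode_design"))
  W_pool <- as.matrix(W_pool)
  if (is.null(design$alpha_A) || is.null(design$alpha_Y)) {
    design <- calibrate_design(design, W_pool)
  }
  n <- nrow(W_pool)
  if (!is.null(mc_draws) && mc_draws < n) {
    set.seed(derive_seed(design$seed, "true_effect"))
    W_pool <- W_pool[sample.int(n, mc_draws, replace = TRUE), , drop = FALSE]
    exact <- FALSE
  } else {
    exact <- TRUE
  }
  lp_Y <- design$alpha_Y + .design_lp(W_pool, design$outcome_coefficients)
  diff <- stats::plogis(lp_Y + design$treatment_effect) - stats::plogis(lp_Y)
  structure(list(
    psi_true = mean(diff),
    mc_standard_error = if (exact) 0 else stats::sd(diff) / sqrt(length(diff))
  ), class = "true_effect")
}

#' Generate the full set of plasmode replicates
#'
#' Calibrates the design once against the source covariate pool, then
#' produces `n_replicates` independent replicates with deterministically
#' derived per-replicate seeds.
#'
#' @param source a [cohort_data()] (only `W` is used) or covariate matrix.
#' @param design a `plasmode_design`.
#' @return a list of `plasmode_replicate` objects.
#' @export
run_replicates <- function(source, design) {
  W <- if (inherits(source, "cohort_data")) source$W else as.matrix(source)
  design <- calibrate_design(design, W)
  lapply(seq_len(design$n_replicates), function(r) {
    rs <- derive_seed(design$seed, "replicate", r)
    W_boot <- bootstrap_covariates(W, design$n_per_replicate,
                                   seed = derive_seed(rs, "bootstrap"))
    inject_mechanisms(W_boot, design, replicate_seed = rs)
  })
}
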