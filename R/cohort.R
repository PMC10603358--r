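#' Specify a synthetic claims/EHR-like cohort
#'
#' Describes the data-generating process for a synthetic new-user cohort
#' emulating a linked claims/EHR study: a binary treatment `A` (active
#' comparator design, ~36/64 split), a rare binary outcome `Y` (~4% events),
#' light missingness of the outcome through an MCAR censoring indicator `C`,
#' a small block of investigator-specified covariates, and a large block of
#' sparse binary "proxy" features that are noisy threshold indicators of
#' latent Gaussian confounders. Confounding of the A-Y relationship flows
#' through the latent variables; the proxies carry that signal imperfectly,
#' which is the phenomenon the high-dimensional adjustment methods target.
#'
#' @param n_subjects number of subjects.
#' @param n_investigator_covariates number of investigator-specified
#'   covariates (half continuous, half binary).
#' @param n_proxy_features number of sparse binary proxy features; proxy
#'   prevalences are drawn log-uniformly on `[0.001, 0.3]` so that
#'   prevalence screening at 0.001 is exercised.
#' @param n_latent_confounders number of latent standard-normal confounders.
#' @param target_treatment_prevalence marginal `P(A = 1)` the intercept is
#'   calibrated to.
#' @param target_outcome_rate marginal `P(Y = 1)` (before censoring) the
#'   intercept is calibrated to.
#' @param censoring_rate `P(C = 0)`, independent of everything (MCAR).
#' @param confounding_strengths numeric vector of per-latent log-odds
#'   coefficients used in both the treatment and outcome models; recycled to
#'   `n_latent_confounders`. All zeros gives a randomized, unconfounded DGP.
#' @param treatment_log_or log-odds effect of `A` in the outcome model.
#' @param proxy_noise probability in `[0, 0.5)` that a truly positive proxy
#'   indicator goes unrecorded (a false-negative rate), degrading proxies
#'   from deterministic to noisy reflections of the latent confounders.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        n_investigator_covariates = 20L,
                        n_proxy_features = 200L,
                        n_latent_confounders = 4L,
                        target_treatment_prevalence = 0.364,
                        target_outcome_rate = 0.042,
                        censoring_rate = 0.04,
                        confounding_strengths = 0.5,
                        treatment_log_or = 0.4,
                        proxy_noise = 0.05,
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1, n_investigator_covariates >= 0, n_proxy_features >= 0,
    n_latent_confounders >= 1,
    target_treatment_prevalence > 0, target_treatment_prevalence < 1,
    target_outcome_rate > 0, target_outcome_rate < 1,
    censoring_rate >= 0, censoring_rate < 1,
    proxy_noise >= 0, proxy_noise < 0.5,
    is.numeric(confounding_strengths)
  )
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_investigator_covariates = as.integer(n_investigator_covariates),
    n_proxy_features = as.integer(n_proxy_features),
    n_latent_confounders = as.integer(n_latent_confounders),
    target_treatment_prevalence = target_treatment_prevalence,
    target_outcome_rate = target_outcome_rate,
    censoring_rate = censoring_rate,
    confounding_strengths = rep_len(confounding_strengths, n_latent_confounders),
    treatment_log_or = treatment_log_or,
    proxy_noise = proxy_noise,
    seed = as.integer(seed)
  )
  structure(spec, class = "cohort_spec")
}

#' Construct a cohort data object
#'
#' Container for one analysis cohort: covariate matrix `W`, binary treatment
#' `A`, binary outcome `Y` (NA exactly where the censoring indicator `C` is
#' 0), and optional latent confounders kept only for simulation diagnostics.
#'
#' @param W numeric matrix with unique column names.
#' @param A,C binary vectors of length `nrow(W)`.
#' @param Y binary vector, NA allowed only where `C == 0`.
#' @param latent optional matrix of latent confounders.
#' @return an object of class `cohort_data`.
#' @export
cohort_data <- function(W, A, Y, C = rep(1L, length(A)), latent = NULL) {
  W <- as.matrix(W)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  stopifnot(
    nrow(W) == length(A), length(A) == length(Y), length(Y) == length(C),
    !anyNA(W), !anyNA(A), !anyNA(C),
    all(A %in% c(0, 1)), all(C %in% c(0, 1)),
    all(Y %in% c(0, 1) | is.na(Y)),
    !anyDuplicated(colnames(W))
  )
  if (any(is.na(Y) & C == 1)) stop("Y may be missing only where C = 0")
  structure(
    list(W = W, A = as.integer(A), Y = as.integer(Y), C = as.integer(C),
         column_names = colnames(W), latent = latent),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf(
    "<cohort_data> %d subjects, %d covariates | treated %.1f%% | events %.1f%% | censored %.1f%%\n",
    length(x$A), ncol(x$W), 100 * mean(x$A),
    100 * mean(x$Y[x$C == 1]), 100 * mean(x$C == 0)
  ))
  invisible(x)
}

#' Calibrate a logistic-model intercept to a target marginal rate
#'
#' Solves for the intercept `a` such that `mean(plogis(a + lp)) == target`
#' by monotone root-finding. Used to pin marginal treatment prevalence and
#' outcome rate in the synthetic cohort and plasmode designs.
#'
#' @param linear_predictor numeric vector of log-odds contributions.
#' @param target_rate target marginal probability in (0, 1).
#' @param label name used in error messages when the target is unreachable.
#' @return the intercept (log-odds scalar).
#' @export
calibrate_intercept <- function(linear_predictor, target_rate, label = "rate") {
  stopifnot(target_rate > 0, target_rate < 1)
  if (!all(is.finite(linear_predictor))) {
    stop(sprintf("calibration failure for target '%s': non-finite linear predictor", label))
  }
  f <- function(a) mean(stats::plogis(a + linear_predictor)) - target_rate
  m <- max(abs(linear_predictor), 1)
  lo <- stats::qlogis(target_rate) - m - 1
  hi <- stats::qlogis(target_rate) + m + 1
  root <- tryCatch(
    stats::uniroot(f, c(lo, hi), extendInt = "upX", tol = 1e-12)$root,
    error = function(e) stop(sprintf(
      "calibration failure for target '%s' (%.4g): %s", label, target_rate,
      conditionMessage(e)
    ))
  )
  if (abs(f(root)) > 1e-6) {
    stop(sprintf("calibration failure for target '%s': achieved rate off by %.2g",
                 label, abs(f(root))))
  }
  root
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from the DGP declared in [cohort_spec()]: latent
#' Gaussian confounders; investigator covariates that are noisy linear
#' (continuous) or thresholded (binary) functions of the latents; sparse
#' binary proxies that are noisy threshold indicators of single latents;
#' logistic treatment and outcome models whose intercepts are calibrated to
#' the target marginal rates; MCAR censoring applied after outcome
#' generation, masking `Y` where `C = 0`.
#'
#' @param spec a [cohort_spec()].
#' @return a [cohort_data()] object (with `latent` retained).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  q <- spec$n_latent_confounders
  Z <- matrix(stats::rnorm(n * q), n, q)

  # investigator covariates: first half continuous, second half binary
  k <- spec$n_investigator_covariates
  Xi <- NULL
  if (k > 0) {
    Xi <- matrix(0, n, k)
    n_cont <- ceiling(k / 2)
    for (j in seq_len(k)) {
      l <- ((j - 1) %% q) + 1
      if (j <= n_cont) {
        Xi[, j] <- 0.6 * Z[, l] + stats::rnorm(n, sd = 0.8)
      } else {
        pj <- stats::runif(1, 0.05, 0.5)
        latent_part <- 0.8 * Z[, l] + stats::rnorm(n, sd = 0.6)
        thr <- stats::qnorm(1 - pj, sd = 1)
        Xi[, j] <- as.integer(latent_part > thr)
      }
    }
    colnames(Xi) <- sprintf("inv_%03d", seq_len(k))
  }

  # sparse binary proxies: noisy indicators of single latents; noise acts
  # as a false-negative (masking) rate so the claims-like prevalence
  # spectrum, including sub-0.001 codes, is preserved
  p <- spec$n_proxy_features
  Xp <- NULL
  if (p > 0) {
    prev <- exp(stats::runif(p, log(0.001), log(0.3)))
    l_of <- ((seq_len(p) - 1) %% q) + 1
    base <- Z[, l_of, drop = FALSE] > matrix(stats::qnorm(1 - prev), n, p, byrow = TRUE)
    recorded <- matrix(stats::runif(n * p) >= spec$proxy_noise, n, p)
    Xp <- matrix(as.integer(base & recorded), n, p)
    colnames(Xp) <- sprintf("proxy_%04d", seq_len(p))
  }

  W <- cbind(Xi, Xp)
  if (is.null(W)) stop("cohort must have at least one covariate")

  # investigator-covariate effects scale with the confounding strength so
  # that zero strength yields a fully randomized, unconfounded design
  inv_scale <- 0.3 * mean(abs(spec$confounding_strengths))
  inv_coef <- if (k > 0) inv_scale * rep_len(c(1, -1), k) else numeric(0)
  lp_A <- drop(Z %*% spec$confounding_strengths) +
    if (k > 0) drop(Xi %*% inv_coef) else 0
  a_A <- calibrate_intercept(lp_A, spec$target_treatment_prevalence,
                             "target_treatment_prevalence")
  A <- as.integer(stats::runif(n) < stats::plogis(a_A + lp_A))

  lp_Y <- drop(Z %*% spec$confounding_strengths) +
    (if (k > 0) drop(Xi %*% inv_coef) else 0) +
    spec$treatment_log_or * A
  a_Y <- calibrate_intercept(lp_Y, spec$target_outcome_rate, "target_outcome_rate")
  Y <- as.integer(stats::runif(n) < stats::plogis(a_Y + lp_Y))

  C <- as.integer(stats::runif(n) >= spec$censoring_rate)
  Y[C == 0] <- NA_integer_

  cohort_data(W, A, Y, C, latent = Z)
}

#' Drop rare binary covariates by prevalence screening
#'
#' Removes binary columns of `W` whose mean is strictly below `threshold`;
#' non-binary (continuous) columns are never touched and column order is
#' preserved. Mirrors the claims-code screening step applied before
#' high-dimensional adjustment.
#'
#' @param cohort a [cohort_data()].
#' @param threshold prevalence threshold in `[0, 1]` (default 0.001).
#' @return the screened [cohort_data()].
#' @export
screen_prevalence <- function(cohort, threshold = 0.001) {
  stopifnot(inherits(cohort, "cohort_data"), threshold >= 0, threshold <= 1)
  W <- cohort$W
  keep <- vapply(seq_len(ncol(W)), function(j) {
    x <- W[, j]
    !is_binary_col(x) || mean(x) >= threshold
  }, logical(1))
  cohort_data(W[, keep, drop = FALSE], cohort$A, cohort$Y, cohort$C,
              latent = cohort$latent)
}

#' Cohort summary from raw counts
#'
#' Emits the standard cohort descriptive line: treated and comparator counts
#' with percentages (one-decimal rounding) and the event count among all
#' subjects.
#'
#' @param n_total cohort size.
#' @param n_treated number of treated (index-drug) initiators.
#' @param n_events number of outcome events.
#' @return a data.frame with columns `group`, `n`, `pct`.
#' @export
summarize_cohort_counts <- function(n_total, n_treated, n_events) {
  stopifnot(n_total > 0, n_treated >= 0, n_treated <= n_total,
            n_events >= 0, n_events <= n_total)
  data.frame(
    group = c("treated", "comparator", "events"),
    n = c(n_treated, n_total - n_treated, n_events),
    pct = round(100 * c(n_treated, n_total - n_treated, n_events) / n_total, 1)
  )
}

#' Cohort summary for a cohort_data object
#'
#' @param cohort a [cohort_data()].
#' @return see [summarize_cohort_counts()]; events counted among observed
#'   (`C = 1`) subjects, denominator the full cohort.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  summarize_cohort_counts(
    n_total = length(cohort$A),
    n_treated = sum(cohort$A),
    n_events = sum(cohort$Y == 1, na.rm = TRUE)
  )
}

#' Write / read the cohort CSV dialect
#'
#' Columns `id, A, Y, C, <covariates>`; `Y` empty where `C = 0`; UTF-8 with
#' a header row.
#'
#' @param cohort a [cohort_data()].
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a [cohort_data()].
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  dt <- data.table::data.table(
    id = seq_along(cohort$A), A = cohort$A, Y = cohort$Y, C = cohort$C
  )
  dt <- cbind(dt, data.table::as.data.table(cohort$W))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("id", "A", "Y", "C")
  if (!all(req %in% names(dt))) {
    stop("cohort CSV must have columns id, A, Y, C")
  }
  covs <- setdiff(names(dt), req)
  cohort_data(as.matrix(dt[, covs, with = FALSE]), dt$A, dt$Y, dt$C)
}
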