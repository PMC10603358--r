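#' Restrict a cohort to complete cases
#'
#' Drops rows whose outcome is censored (`C = 0`), the complete-case
#' analysis justified by the MCAR censoring assumption.
#'
#' @param data a [cohort_data()].
#' @return the complete-case [cohort_data()].
#' @export
complete_case <- function(data) {
  stopifnot(inherits(data, "cohort_data"))
  keep <- which(data$C == 1)
  if (length(keep) == 0) stop("all rows censored: no complete cases")
  if (length(keep) == length(data$A)) return(data)
  .subset_cohort(data, keep)
}

#' Construct an initial outcome regression object
#'
#' Holds per-subject predictions `Q(1, W)` and `Q(0, W)` of the outcome
#' regression under each treatment, bounded into (0, 1). Use this
#' constructor directly to supply an externally fitted (e.g. saturated)
#' outcome model.
#'
#' @param Q1,Q0 numeric vectors of predicted outcome probabilities under
#'   treatment and control.
#' @param coefficients,selected_lambda optional fit metadata.
#' @param fit optional underlying model object.
#' @return an object of class `outcome_fit`.
#' @export
outcome_fit <- function(Q1, Q0, coefficients = NULL, selected_lambda = NA_real_,
                        fit = NULL) {
  stopifnot(length(Q1) == length(Q0))
  structure(list(
    Q1 = bound(Q1, 1e-6, 1 - 1e-6),
    Q0 = bound(Q0, 1e-6, 1 - 1e-6),
    coefficients = coefficients,
    selected_lambda = selected_lambda,
    .fit = fit
  ), class = "outcome_fit")
}

#' Fit the initial outcome regression by cross-validated Lasso
#'
#' L1-penalized logistic regression of the outcome on treatment and
#' covariates over complete cases, lambda by cross-validated binomial
#' deviance. The treatment indicator is unpenalized so rare-event shrinkage
#' cannot drop it. Predictions are produced with treatment set to 1 and 0
#' for every subject.
#'
#' @param data a [cohort_data()] (censored rows are dropped internally).
#' @param control a [ps_control()] (outcome-path settings are used).
#' @param seed integer seed (fold assignment).
#' @param lambda optional fixed lambda overriding cross-validation.
#' @return an [outcome_fit()].
#' @export
fit_initial_outcome <- function(data, control = ps_control(), seed = 1L,
                                lambda = NULL) {
  data <- complete_case(data)
  if (length(unique(data$Y)) < 2) stop("outcome model requires both outcome classes")
  X <- cbind(A = data$A, data$W)
  Xs <- as_sparse(X)
  pf <- c(0, rep(1, ncol(data$W)))
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Xs, data$Y, family = "binomial",
                          nlambda = control$outcome_nlambda,
                          lambda.min.ratio = control$outcome_lambda_min_ratio,
                          thresh = control$thresh, penalty.factor = pf)
    s <- bound(lambda, min(fit$lambda), max(fit$lambda))
  } else {
    foldid <- make_folds(length(data$Y), control$cv_folds, strata = data$Y,
                         seed = derive_seed(seed, "q_cv"))
    fit <- glmnet::cv.glmnet(Xs, data$Y, family = "binomial", foldid = foldid,
                             nlambda = control$outcome_nlambda,
                             lambda.min.ratio = control$outcome_lambda_min_ratio,
                             thresh = control$thresh, penalty.factor = pf)
    s <- fit$lambda.min
  }
  X1 <- Xs; X1[, 1] <- 1
  X0 <- Xs; X0[, 1] <- 0
  beta <- stats::coef(fit, s = s)
  nz <- which(beta[-1, 1] != 0)
  outcome_fit(
    Q1 = drop(stats::predict(fit, newx = X1, s = s, type = "response")),
    Q0 = drop(stats::predict(fit, newx = X0, s = s, type = "response")),
    coefficients = stats::setNames(beta[-1, 1][nz], rownames(beta)[-1][nz]),
    selected_lambda = s, fit = fit
  )
}

.as_scores <- function(g, n) {
  s <- if (inherits(g, "ps_fit")) g$scores else g
  if (length(s) == 1) s <- rep(s, n)
  stopifnot(length(s) == n, all(s > 0 & s < 1))
  s
}

.as_qfit <- function(q, data, control, seed) {
  if (is.null(q)) return(fit_initial_outcome(data, control, seed))
  if (inherits(q, "outcome_fit")) return(q)
  if (is.list(q) && all(c("Q1", "Q0") %in% names(q))) {
    return(outcome_fit(q$Q1, q$Q0))
  }
  stop("q must be an outcome_fit or a list with Q1 and Q0")
}

#' TMLE targeting step: one-parameter logistic fluctuation
#'
#' Updates the initial outcome regression along the least-favorable
#' submodel `logit Q*(A, W) = logit Q(A, W) + eps * H(A, W)` with clever
#' covariate `H(A, W) = A / g(W) - (1 - A) / (1 - g(W))`, fitting `eps` by
#' maximum likelihood (Newton-Raphson). After the update the empirical
#' score equation `mean(H * (Y - Q*))` holds to below 1e-8.
#'
#' @param q an [outcome_fit()].
#' @param g a `ps_fit` or a numeric vector/scalar of truncated propensity
#'   scores.
#' @param data a [cohort_data()] of complete cases.
#' @param tol convergence tolerance on the mean score.
#' @param max_iter maximum Newton iterations.
#' @return a list: `epsilon`, `Q1_star`, `Q0_star`, `score_residual`.
#' @export
fluctuate <- function(q, g, data, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(data, "cohort_data"))
  A <- data$A
  Y <- data$Y
  n <- length(A)
  gs <- .as_scores(g, n)
  H1 <- 1 / gs
  H0 <- -1 / (1 - gs)
  H <- ifelse(A == 1, H1, H0)
  off <- stats::qlogis(bound(ifelse(A == 1, q$Q1, q$Q0), 1e-6, 1 - 1e-6))
  eps <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- stats::plogis(off + eps * H)
    score <- mean(H * (Y - P))
    if (abs(score) < tol) { converged <- TRUE; break }
    info <- mean(H^2 * P * (1 - P))
    if (info < 1e-14) break
    eps <- bound(eps + score / info, -100, 100)
  }
  P <- stats::plogis(off + eps * H)
  resid <- mean(H * (Y - P))
  if (!converged && abs(resid) > 1e-8) {
    stop(sprintf(
      "fluctuation did not converge: epsilon = %.4g, mean score = %.3g after %d iterations",
      eps, resid, max_iter
    ))
  }
  list(
    epsilon = eps,
    Q1_star = stats::plogis(stats::qlogis(q$Q1) + eps * H1),
    Q0_star = stats::plogis(stats::qlogis(q$Q0) + eps * H0),
    score_residual = resid
  )
}

.new_tmle_result <- function(model_id, psi, se, epsilon, eif_mean, n_used) {
  structure(list(
    model_id = model_id,
    psi_hat = psi,
    standard_error = se,
    ci_lower = psi - 1.96 * se,
    ci_upper = psi + 1.96 * se,
    epsilon = epsilon,
    eif_mean = eif_mean,
    n_used = as.integer(n_used)
  ), class = "tmle_result")
}

#' @export
print.tmle_result <- function(x, ...) {
  cat(sprintf(
    "Risk difference %.4f (95%% CI %.4f, %.4f), SE %.4f, n = %d\n",
    x$psi_hat, x$ci_lower, x$ci_upper, x$standard_error, x$n_used
  ))
  invisible(x)
}

#' TMLE of the marginal risk difference
#'
#' Targeted minimum loss-based estimation of the average treatment effect
#' on the risk-difference scale: initial outcome regression (cross-validated
#' Lasso unless supplied), one-parameter logistic fluctuation against the
#' given propensity scores, plug-in estimate
#' `psi = mean(Q*(1, W) - Q*(0, W))`, and influence-curve inference with
#' `EIF_i = H(A_i, W_i) (Y_i - Q*(A_i, W_i)) + Q*(1, W_i) - Q*(0, W_i) - psi`,
#' `SE = sd(EIF) / sqrt(n)`, 95% Wald interval.
#'
#' @param data a [cohort_data()]; censored rows are dropped.
#' @param g a `ps_fit` (or numeric truncated scores) for the complete-case
#'   rows.
#' @param q optional [outcome_fit()] (or list with `Q1`, `Q0`); fitted by
#'   [fit_initial_outcome()] when `NULL`.
#' @param control a [ps_control()].
#' @param seed integer seed for the internal outcome fit.
#' @return a `tmle_result`.
#' @export
estimate_ate <- function(data, g, q = NULL, control = ps_control(), seed = 1L) {
  data <- complete_case(data)
  n <- length(data$A)
  q <- .as_qfit(q, data, control, seed)
  gs <- .as_scores(g, n)
  fl <- fluctuate(q, gs, data)
  psi <- mean(fl$Q1_star - fl$Q0_star)
  H <- ifelse(data$A == 1, 1 / gs, -1 / (1 - gs))
  Qa_star <- ifelse(data$A == 1, fl$Q1_star, fl$Q0_star)
  eif <- H * (data$Y - Qa_star) + fl$Q1_star - fl$Q0_star - psi
  se <- stats::sd(eif) / sqrt(n)
  .new_tmle_result(
    model_id = if (inherits(g, "ps_fit")) g$model_id else NA_integer_,
    psi = psi, se = se, epsilon = fl$epsilon,
    eif_mean = mean(eif), n_used = n
  )
}

#' Unadjusted risk difference
#'
#' Difference in event proportions between arms over complete cases, with
#' the two-proportion Wald standard error and 95% interval. Returned in the
#' same shape as a TMLE result (`epsilon` and `eif_mean` are `NA`).
#'
#' @param data a [cohort_data()].
#' @return a `tmle_result`-shaped summary.
#' @export
unadjusted_rd <- function(data) {
  data <- complete_case(data)
  n1 <- sum(data$A == 1)
  n0 <- sum(data$A == 0)
  if (n1 == 0 || n0 == 0) stop("unadjusted_rd requires both treatment arms")
  p1 <- mean(data$Y[data$A == 1])
  p0 <- mean(data$Y[data$A == 0])
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  .new_tmle_result(model_id = 0L, psi = p1 - p0, se = se,
                   epsilon = NA_real_, eif_mean = NA_real_, n_used = n1 + n0)
}
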