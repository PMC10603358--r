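#' Control parameters for propensity-score and outcome Lasso fits
#'
#' Defaults: 10-fold cross-validation for lambda selection, 5 folds for
#' cross-fitting and for the collaborative loss; treatment-model lambda path
#' of 100 values spanning 4 decades below the data-derived maximum;
#' outcome-model paths are shallower (50 values, 2 decades) because with
#' rare binary outcomes the deep end of the path approaches separation and
#' is never selected (30 values, lambda.min.ratio 0.05); coordinate-descent
#' convergence threshold 1e-5; propensity-score truncation bound 0.01.
#'
#' @param cv_folds folds for cross-validated lambda selection.
#' @param crossfit_folds folds for cross-fitting (Models 5-8).
#' @param collab_folds folds for the collaborative cross-validated loss.
#' @param nlambda,lambda_min_ratio treatment-model lambda path.
#' @param outcome_nlambda,outcome_lambda_min_ratio outcome-model lambda path.
#' @param thresh glmnet convergence threshold.
#' @param truncation propensity-score truncation bound in `[0, 0.5)`.
#' @return a list of class `ps_control`.
#' @export
ps_control <- function(cv_folds = 10L, crossfit_folds = 5L, collab_folds = 5L,
                       nlambda = 100L, lambda_min_ratio = 1e-4,
                       outcome_nlambda = 30L, outcome_lambda_min_ratio = 0.05,
                       thresh = 1e-5, truncation = 0.01) {
  stopifnot(cv_folds >= 2, crossfit_folds >= 2, collab_folds >= 2,
            truncation >= 0, truncation < 0.5)
  structure(as.list(environment()), class = "ps_control")
}

#' Truncate propensity scores away from 0 and 1
#'
#' Elementwise clamp to `[bound, 1 - bound]`, the usual numerical guard for
#' the positivity assumption.
#'
#' @param scores numeric vector (or matrix) of probabilities.
#' @param bound truncation bound in `[0, 0.5)`.
#' @return truncated scores.
#' @export
truncate_scores <- function(scores, bound) {
  stopifnot(bound >= 0, bound < 0.5)
  bound(scores, bound, 1 - bound)
}

.check_arms <- function(A, context = "data") {
  if (sum(A == 1) < 2 || sum(A == 0) < 2) {
    stop(sprintf("%s must contain at least 2 subjects in each treatment arm", context))
  }
}

.subset_cohort <- function(data, idx) {
  cohort_data(data$W[idx, , drop = FALSE], data$A[idx], data$Y[idx], data$C[idx])
}

.new_ps_fit <- function(model_id, fit_obj, s, scores, penalty_weights, data,
                        control, fold_assignment = NULL, extra = list()) {
  cf <- NULL
  if (!is.null(fit_obj)) {
    beta <- stats::coef(fit_obj, s = s)
    nz <- which(beta[-1, 1] != 0)
    cf <- stats::setNames(beta[-1, 1][nz], rownames(beta)[-1][nz])
  }
  structure(c(list(
    model_id = as.integer(model_id),
    coefficients = cf,
    selected_lambda = s,
    penalty_weights = penalty_weights,
    scores = truncate_scores(scores, control$truncation),
    crossfit_fold_assignment = fold_assignment,
    truncation_bound = control$truncation,
    .fit = fit_obj
  ), extra), class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf(
    "<ps_fit> Model %d | lambda %.4g | %s nonzero | scores in [%.3f, %.3f]\n",
    x$model_id, mean(x$selected_lambda),
    if (is.null(x$coefficients)) "per-fold" else length(x$coefficients),
    min(x$scores), max(x$scores)
  ))
  invisible(x)
}

#' Model 1: cross-validated Lasso propensity score
#'
#' L1-penalized logistic regression of treatment on covariates with lambda
#' chosen to minimize K-fold cross-validated binomial deviance for
#' treatment prediction. Scores are the fitted probabilities, truncated.
#'
#' @param data a [cohort_data()].
#' @param control a [ps_control()].
#' @param seed integer seed (fold assignment).
#' @param penalty_factor optional 0/1 vector over columns (0 = unpenalized,
#'   forced in); used by the outcome-adaptive variant.
#' @param lambda optional fixed lambda overriding cross-validated selection
#'   (clamped to the computed path).
#' @return a `ps_fit`.
#' @export
fit_lasso_ps <- function(data, control = ps_control(), seed = 1L,
                         penalty_factor = NULL, lambda = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  .check_arms(data$A)
  Ws <- as_sparse(data$W)
  p <- ncol(Ws)
  pf <- penalty_factor %||% rep(1, p)
  pw <- stats::setNames(as.integer(pf == 0) * 0L + as.integer(pf != 0), colnames(data$W))
  model_id <- if (any(pf == 0)) 2L else 1L
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Ws, data$A, family = "binomial",
                          nlambda = control$nlambda,
                          lambda.min.ratio = control$lambda_min_ratio,
                          thresh = control$thresh, penalty.factor = pf)
    s <- bound(lambda, min(fit$lambda), max(fit$lambda))
  } else {
    foldid <- make_folds(length(data$A), control$cv_folds, strata = data$A,
                         seed = derive_seed(seed, "treatment_cv"))
    fit <- glmnet::cv.glmnet(Ws, data$A, family = "binomial", foldid = foldid,
                             nlambda = control$nlambda,
                             lambda.min.ratio = control$lambda_min_ratio,
                             thresh = control$thresh, penalty.factor = pf)
    s <- fit$lambda.min
  }
  scores <- drop(stats::predict(fit, newx = Ws, s = s, type = "response"))
  .new_ps_fit(model_id, fit, s, scores, pw, data, control)
}

# CV Lasso of Y on W over complete cases; returns names of columns with
# nonzero coefficients at lambda.min (the outcome active set)
outcome_active_set <- function(data, control = ps_control(), seed = 1L) {
  obs <- which(data$C == 1)
  Y <- data$Y[obs]
  if (length(unique(Y)) < 2) stop("outcome lasso requires both outcome classes")
  Ws <- as_sparse(data$W[obs, , drop = FALSE])
  foldid <- make_folds(length(Y), control$cv_folds, strata = Y,
                       seed = derive_seed(seed, "outcome_lasso"))
  fit <- glmnet::cv.glmnet(Ws, Y, family = "binomial", foldid = foldid,
                           nlambda = control$outcome_nlambda,
                           lambda.min.ratio = control$outcome_lambda_min_ratio,
                           thresh = control$thresh)
  beta <- stats::coef(fit, s = "lambda.min")
  rownames(beta)[-1][beta[-1, 1] != 0]
}

#' Model 2: outcome-adaptive Lasso propensity score
#'
#' Two steps: (1) a cross-validated Lasso of the outcome on the covariates
#' (complete cases) identifies the outcome active set — all covariates whose
#' coefficient is not shrunk to zero; (2) an adaptive Lasso of treatment on
#' the covariates assigns penalization weight zero to active-set columns
#' (forcing them into the model) and weight one to the rest, with lambda
#' again chosen by cross-validated treatment prediction. With an empty
#' active set this reduces exactly to Model 1.
#'
#' @inheritParams fit_lasso_ps
#' @return a `ps_fit` with `penalty_weights` recording the 0/1 map.
#' @export
fit_outcome_adaptive_ps <- function(data, control = ps_control(), seed = 1L) {
  active <- outcome_active_set(data, control, seed)
  pf <- ifelse(colnames(data$W) %in% active, 0, 1)
  fit <- fit_lasso_ps(data, control, seed, penalty_factor = pf)
  fit$model_id <- 2L
  fit
}

# one-parameter logistic fluctuation fit, vectorized over the columns of H:
# for each column l, solves max-likelihood epsilon_l in
#   logit P = off + epsilon_l * H[, l]
# by Newton-Raphson on the training rows. Returns the epsilon vector.
.fit_eps_matrix <- function(H, Y, off, rows, tol = 1e-10, max_iter = 40L) {
  Ht <- H[rows, , drop = FALSE]
  Yt <- Y[rows]
  ot <- off[rows]
  L <- ncol(Ht)
  eps <- rep(0, L)
  active <- seq_len(L)  # columns not yet converged
  for (it in seq_len(max_iter)) {
    Ha <- Ht[, active, drop = FALSE]
    eta <- ot + sweep(Ha, 2, eps[active], `*`)
    P <- 1 / (1 + exp(-eta))
    score <- colMeans(Ha * (Yt - P))
    info <- colMeans(Ha^2 * P * (1 - P))
    eps[active] <- bound(eps[active] + score / pmax(info, 1e-12), -50, 50)
    active <- active[abs(score) >= tol]
    if (length(active) == 0) break
  }
  eps
}

#' Collaborative selection of the Lasso regularization strength
#'
#' The collaborative-controlled criterion: instead of choosing lambda by
#' treatment prediction, each candidate lambda's propensity scores are used
#' to run the TMLE fluctuation of a fixed initial outcome regression, and
#' the V-fold cross-validated negative log-likelihood of the fluctuated
#' outcome regression is recorded (fluctuation coefficient fit on training
#' folds, likelihood evaluated on the validation fold). The lambda
#' minimizing this collaborative loss is returned; exact ties go to the
#' largest (most regularized) lambda.
#'
#' @param lambdas decreasing lambda path.
#' @param score_matrix `n x length(lambdas)` matrix of candidate propensity
#'   scores (already truncated).
#' @param data a [cohort_data()] (complete cases).
#' @param q_init an [outcome_fit()] fitted on the same rows.
#' @param control a [ps_control()].
#' @param seed integer seed (fold assignment for the loss).
#' @return a list: `lambda`, `index`, `lambdas`, `criterion_values`,
#'   `criterion_kind = "collaborative_loss"`.
#' @export
collab_select_lambda <- function(lambdas, score_matrix, data, q_init,
                                 control = ps_control(), seed = 1L) {
  stopifnot(length(lambdas) >= 1, ncol(score_matrix) == length(lambdas),
            !is.unsorted(rev(lambdas), strictly = TRUE))
  A <- data$A
  Y <- data$Y
  n <- length(A)
  Qa <- ifelse(A == 1, q_init$Q1, q_init$Q0)
  off <- stats::qlogis(bound(Qa, 1e-6, 1 - 1e-6))
  H <- score_matrix
  H[A == 1, ] <- 1 / score_matrix[A == 1, , drop = FALSE]
  H[A == 0, ] <- -1 / (1 - score_matrix[A == 0, , drop = FALSE])
  folds <- make_folds(n, control$collab_folds, strata = Y,
                      seed = derive_seed(seed, "collab_cv"))
  nll <- rep(0, length(lambdas))
  for (v in seq_len(control$collab_folds)) {
    train <- which(folds != v)
    val <- which(folds == v)
    eps <- .fit_eps_matrix(H, Y, off, train)
    Pv <- stats::plogis(off[val] + sweep(H[val, , drop = FALSE], 2, eps, `*`))
    Pv <- bound(Pv, 1e-12, 1 - 1e-12)
    nll <- nll - colSums(log(Pv) * Y[val] + log(1 - Pv) * (1 - Y[val]))
  }
  nll <- nll / n
  if (!any(is.finite(nll))) stop("collaborative loss non-finite at every lambda")
  nll[!is.finite(nll)] <- Inf
  idx <- which.min(nll)  # path is decreasing: first minimum = largest lambda
  list(lambda = lambdas[idx], index = idx, lambdas = lambdas,
       criterion_values = nll, criterion_kind = "collaborative_loss")
}

# shared engine for Models 3 and 4: glmnet treatment path (with optional
# forced-inclusion penalty factors), collaborative lambda selection
.fit_collab_engine <- function(data, q_init, control, seed, penalty_factor,
                               model_id) {
  .check_arms(data$A)
  Ws <- as_sparse(data$W)
  pf <- penalty_factor %||% rep(1, ncol(Ws))
  fit <- glmnet::glmnet(Ws, data$A, family = "binomial",
                        nlambda = control$nlambda,
                        lambda.min.ratio = control$lambda_min_ratio,
                        thresh = control$thresh, penalty.factor = pf)
  scores <- stats::predict(fit, newx = Ws, type = "response")
  scores <- truncate_scores(scores, control$truncation)
  sel <- collab_select_lambda(fit$lambda, scores, data, q_init, control, seed)
  pw <- stats::setNames(as.integer(pf != 0), colnames(data$W))
  .new_ps_fit(model_id, fit, sel$lambda, scores[, sel$index], pw, data, control,
              extra = list(lambda_path = sel$lambdas,
                           criterion_values = sel$criterion_values))
}

#' Model 3: collaborative-controlled Lasso propensity score
#'
#' Model 1's lambda path, with lambda selected by the collaborative loss of
#' [collab_select_lambda()] rather than by treatment prediction.
#'
#' @inheritParams fit_lasso_ps
#' @param q_init an [outcome_fit()] (initial outcome regression) fitted on
#'   the same rows; fitted internally if `NULL`.
#' @return a `ps_fit` carrying the lambda path and criterion values.
#' @export
fit_collab_ps <- function(data, q_init = NULL, control = ps_control(),
                          seed = 1L) {
  q_init <- q_init %||% fit_initial_outcome(data, control, seed)
  .fit_collab_engine(data, q_init, control, seed, NULL, 3L)
}

#' Model 4: collaborative-controlled outcome-adaptive Lasso
#'
#' Model 2's forced-inclusion penalty weights (outcome-selected covariates
#' get penalty zero) combined with collaborative lambda selection. With an
#' empty outcome active set this reduces exactly to Model 3.
#'
#' @inheritParams fit_collab_ps
#' @return a `ps_fit`.
#' @export
fit_collab_oal_ps <- function(data, q_init = NULL, control = ps_control(),
                              seed = 1L) {
  q_init <- q_init %||% fit_initial_outcome(data, control, seed)
  active <- outcome_active_set(data, control, seed)
  pf <- ifelse(colnames(data$W) %in% active, 0, 1)
  .fit_collab_engine(data, q_init, control, seed, pf, 4L)
}

#' Models 5-8: cross-fitted propensity scores
#'
#' Subjects are partitioned into arm-stratified folds; each subject's score
#' comes from the base fitter (Models 1-4, including its internal lambda
#' selection and, for the collaborative variants, its initial outcome
#' regression) trained on all other folds. Fold assignment is recorded in
#' the result.
#'
#' @param data a [cohort_data()].
#' @param base_model_id base fitter, 1-4; the result's `model_id` is
#'   `base_model_id + 4`.
#' @param control a [ps_control()]; `control$crossfit_folds` folds are used.
#' @param seed integer seed (fold assignment and per-fold fits).
#' @return a `ps_fit` with `crossfit_fold_assignment` and per-fold details
#'   in `fold_details`; `selected_lambda` is the mean of per-fold lambdas.
#' @export
crossfit_ps <- function(data, base_model_id, control = ps_control(),
                        seed = 1L) {
  stopifnot(inherits(data, "cohort_data"), base_model_id %in% 1:4)
  n <- length(data$A)
  k <- control$crossfit_folds
  folds <- make_folds(n, k, strata = data$A,
                      seed = derive_seed(seed, "crossfit"))
  scores <- rep(NA_real_, n)
  fold_details <- vector("list", k)
  for (v in seq_len(k)) {
    train <- which(folds != v)
    held <- which(folds == v)
    if (length(unique(data$A[held])) < 2) {
      stop(sprintf("cross-fitting fold %d contains a single treatment arm", v))
    }
    tr <- .subset_cohort(data, train)
    fs <- derive_seed(seed, "fold_fit", v)
    base <- switch(base_model_id,
      fit_lasso_ps(tr, control, fs),
      fit_outcome_adaptive_ps(tr, control, fs),
      fit_collab_ps(tr, NULL, control, fs),
      fit_collab_oal_ps(tr, NULL, control, fs)
    )
    Wh <- as_sparse(data$W[held, , drop = FALSE])
    scores[held] <- drop(stats::predict(base$.fit, newx = Wh,
                                        s = base$selected_lambda,
                                        type = "response"))
    fold_details[[v]] <- list(lambda = base$selected_lambda,
                              coefficients = base$coefficients,
                              penalty_weights = base$penalty_weights)
  }
  out <- .new_ps_fit(base_model_id + 4L, NULL,
                     mean(vapply(fold_details, `[[`, numeric(1), "lambda")),
                     scores, NULL, data, control, fold_assignment = folds,
                     extra = list(fold_details = fold_details))
  out
}

#' Fit any of the eight propensity-score models
#'
#' Dispatcher over the model taxonomy: 1 = CV Lasso, 2 = outcome-adaptive
#' Lasso, 3 = collaborative-controlled Lasso, 4 = collaborative-controlled
#' outcome-adaptive Lasso, 5-8 = the same four with cross-fitting.
#'
#' @inheritParams fit_lasso_ps
#' @param model_id integer in 1..8.
#' @param q_init optional [outcome_fit()] for Models 3-4 (fitted internally
#'   if `NULL`; Models 7-8 always fit it within training folds).
#' @return a `ps_fit`.
#' @export
fit_ps <- function(data, model_id, control = ps_control(), seed = 1L,
                   q_init = NULL) {
  stopifnot(model_id %in% 1:8)
  if (model_id <= 4) {
    switch(model_id,
      fit_lasso_ps(data, control, seed),
      fit_outcome_adaptive_ps(data, control, seed),
      fit_collab_ps(data, q_init, control, seed),
      fit_collab_oal_ps(data, q_init, control, seed)
    )
  } else {
    crossfit_ps(data, model_id - 4L, control, seed)
  }
}
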