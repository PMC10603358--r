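# internal helpers shared across modules

#' Derive a child seed from a global seed, a stage label, and an index
#'
#' A single global seed fans out deterministically to per-stage,
#' per-replicate seeds so that pipeline stages are reproducible in
#' isolation. The hash is a simple 31-ary string hash reduced modulo
#' 2^31 - 1; collisions across the handful of stage labels used here are
#' irrelevant.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"plasmode"`.
#' @param index nonnegative integer (replicate, fold, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(stage))) h <- (h * 31 + c) %% m
  h <- (h + as.numeric(index) * 7919) %% m
  as.integer(max(h, 1))
}

# stratified fold assignment: permute within strata, deal out 1..k
make_folds <- function(n, k, strata = NULL, seed = NULL) {
  stopifnot(k >= 2, n >= k)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- rep(1L, n)
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

bound <- function(x, lo, hi) pmin(pmax(x, lo), hi)

as_sparse <- function(W) {
  if (inherits(W, "sparseMatrix")) W else Matrix::Matrix(as.matrix(W), sparse = TRUE)
}

is_binary_col <- function(x) all(x %in% c(0, 1) | is.na(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
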