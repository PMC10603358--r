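# shared fixtures; everything is generated in code at test time

# a quick cross-validation setting used throughout the tests
fast_ctl <- ps_control(cv_folds = 5)

# small synthetic cohort
tiny_cohort <- function(n = 400, p_proxy = 20, seed = 42, ...) {
  generate_cohort(cohort_spec(
    n_subjects = n, n_investigator_covariates = 6, n_proxy_features = p_proxy,
    n_latent_confounders = 2, seed = seed, ...
  ))
}

# two-stratum toy table with known nonparametric g-computation answer:
# stratum w=0: 20 treated (8 events), 20 control (4 events)
# stratum w=1: 20 treated (6 events), 20 control (2 events)
# equal stratum weights, g = 0.5 in each stratum,
# psi = ((0.4 - 0.2) + (0.3 - 0.1)) / 2 = 0.2
toy_table <- function() {
  w <- rep(c(0, 1), each = 40)
  a <- rep(rep(c(1, 0), each = 20), 2)
  y <- c(
    rep(c(1, 0), c(8, 12)), rep(c(1, 0), c(4, 16)),   # w = 0
    rep(c(1, 0), c(6, 14)), rep(c(1, 0), c(2, 18))    # w = 1
  )
  data <- cohort_data(cbind(w = w), a, y)
  q <- outcome_fit(
    Q1 = ifelse(w == 0, 8 / 20, 6 / 20),
    Q0 = ifelse(w == 0, 4 / 20, 2 / 20)
  )
  list(data = data, q = q, g = rep(0.5, 80), psi = 0.2)
}

# randomized cohort whose outcome is pure noise (used to realize the
# empty-outcome-active-set premise of the model nesting equivalences)
noise_outcome_cohort <- function(n = 400, p = 12, seed = 7) {
  set.seed(seed)
  W <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, paste0("w", seq_len(p))))
  A <- rbinom(n, 1, 0.4)
  Y <- rbinom(n, 1, 0.2)
  cohort_data(W, A, Y)
}
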