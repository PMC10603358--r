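#!/usr/bin/env Rscript
# Stage 1: generate the synthetic "observed" cohort.
#
# The cohort emulates the structure of a linked claims/EHR new-user study:
# ~36/64 active-comparator split, ~4% six-month event rate, <4% MCAR
# censoring, a small investigator-specified covariate block, and a large
# block of sparse binary proxy features correlated with latent confounders.
# Proxy features with prevalence < 0.001 are screened out, as is standard
# for claims-code features. Desk scale: n = 5,000 subjects, ~500 covariates.

library(blindps)

cfg <- run_config(
  cohort = cohort_spec(
    n_subjects = 5000,
    n_investigator_covariates = 30,
    n_proxy_features = 470,
    n_latent_confounders = 4,
    target_treatment_prevalence = 0.364,
    target_outcome_rate = 0.042,
    censoring_rate = 0.035,
    seed = 20260901
  ),
  models = 1, out_dir = "results", seed = 20260901
)

cohort <- run_make_cohort(cfg)
print(cohort)
cat("\nCohort summary (counts and one-decimal percentages):\n")
print(cohort_summary(cohort))
cat("\nWrote results/cohort.csv and results/cohort_summary.csv\n")
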