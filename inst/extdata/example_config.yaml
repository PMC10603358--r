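# Example run configuration for blindps::read_run_config()
seed: 20260901
models: [1, 2, 3, 4, 5, 6, 7, 8]
out_dir: results
cohort:
  n_subjects: 5000
  n_investigator_covariates: 30
  n_proxy_features: 470
  n_latent_confounders: 4
  target_treatment_prevalence: 0.364
  target_outcome_rate: 0.042
  censoring_rate: 0.035
  seed: 20260901
design:
  treatment_coefficients: {proxy_0001: 0.5, proxy_0002: -0.5}
  outcome_coefficients: {proxy_0002: 0.7, proxy_0003: -0.7}
  treatment_effect: 0.4
  treatment_intercept_target: 0.364
  outcome_intercept_target: 0.042
  n_per_replicate: 1500
  n_replicates: 20
  seed: 20260902
control:
  cv_folds: 5
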