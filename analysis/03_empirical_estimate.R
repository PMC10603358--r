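#!/usr/bin/env Rscript
# Stage 3: the "empirical" analysis of the synthetic cohort.
#
# Applies the model selected by the outcome-blind simulations (read from
# the stage-2 manifest) to the cohort itself: complete-case TMLE of the
# 6-month risk difference with the chosen propensity-score model, next to
# the unadjusted risk difference.

library(blindps)

manifest <- jsonlite::read_json("results/simulate_manifest.json",
                                simplifyVector = TRUE)
model <- as.integer(manifest$selected_model)
cat(sprintf("Using Model %d, selected by the outcome-blind simulations\n\n",
            model))

cfg <- run_config(
  cohort = "results/cohort.csv",
  models = model,
  control = ps_control(cv_folds = 5),
  out_dir = "results", seed = 20260903
)

res <- run_estimate(cfg)
cat("Unadjusted risk difference:\n")
print(res$unadjusted)
cat(sprintf("\nTMLE risk difference (Model %d propensity score):\n", model))
print(res$tmle)
cat("\nWrote results/estimate.json\n")
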