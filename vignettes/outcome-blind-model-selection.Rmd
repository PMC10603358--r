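---
title: "Outcome-blind selection of high-dimensional propensity-score models for targeted learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-blind selection of high-dimensional propensity-score models for targeted learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Healthcare-database safety studies — new-user, active-comparator cohorts
built from claims and electronic health records — must adjust for
confounding with whatever is measured. Beyond a modest set of
investigator-specified covariates, thousands of sparse binary features
derived from diagnosis, procedure and dispensing codes can serve as *proxy
confounders*: noisy reflections of clinical states that are never recorded
directly. Many Lasso-based strategies exist for folding these
high-dimensional proxies into a propensity score, and none dominates across
databases and questions. `blindps` implements a pipeline for choosing
among eight such strategies *objectively*: simulations that reuse the real
covariate structure but never look at the real treatment–outcome
association, so the choice of model cannot be steered (even accidentally)
by the answer it will produce.

The target of estimation throughout is the marginal 6-month risk
difference for a binary outcome under a binary treatment,
$\psi = E[\,Q(1, W) - Q(0, W)\,]$ with $Q(a, w) = E(Y \mid A = a, W = w)$,
estimated by targeted minimum loss-based estimation (TMLE) on the
complete-case data (censoring is assumed uninformative — missing completely
at random — and censored rows are dropped; the package deliberately does
not model informative censoring).

## The synthetic cohort generator

Because linked claims–EHR cohorts cannot be redistributed, the package
ships a generator (`cohort_spec()`, `generate_cohort()`) whose *marginal*
structure emulates such a study. The data-generating process is declared
openly rather than estimated from any real data:

* latent confounders $Z_1, \dots, Z_q \sim N(0, 1)$;
* investigator covariates: half continuous ($0.6 Z_\ell +$ noise), half
  binary thresholded versions with prevalences drawn uniformly on
  $[0.05, 0.5]$;
* proxy features: binary indicators $\mathbf 1\{Z_\ell > z_{1-p_j}\}$ with
  prevalences $p_j$ drawn log-uniformly on $[0.001, 0.3]$ (matching the
  skew of claims-code prevalences and exercising the 0.001 prevalence
  screen), each positive indicator masked to zero independently with
  probability `proxy_noise` (a false-negative rate, preserving the sparse
  prevalence spectrum) so proxies carry confounder information imperfectly;
* treatment: logistic in the latents (coefficients
  `confounding_strengths`) and the investigator covariates (effects scaled
  by the same strengths, so zero strength yields a randomized design),
  intercept calibrated by monotone root-finding (`calibrate_intercept()`)
  to the target prevalence (default 36.4%, a typical active-comparator
  split in published analgesic cohorts);
* outcome: logistic in the same terms plus a treatment effect
  (`treatment_log_or`), calibrated to the target event rate (default 4.2%);
* censoring: Bernoulli, independent of everything (MCAR), default 4%,
  applied *after* outcome generation with `Y` masked where `C = 0`.

The `treatment_log_or` field (default 0.4) sets the log-odds effect of
treatment in the outcome model, so the synthetic cohort carries a modest
real effect unless it is zeroed.

What the generator does *not* emulate: temporal code structure, care-seeking
dynamics, informative censoring, outcome misclassification, and the
code-to-feature engineering of real claims pipelines. Tests passing on
these cohorts certify the estimation machinery, not performance on any
particular real database.

## Outcome-blind (plasmode) simulation

`plasmode_design()` fixes sparse coefficient maps for a logistic treatment
model and a logistic outcome model over *named columns* of the observed
covariates, plus an injected treatment effect $\beta_A$ on the log-odds
scale. `run_replicates()`:

1. bootstraps whole covariate rows from the source cohort (rows are never
   recombined, preserving the joint covariate structure);
2. draws treatment from the injected model;
3. draws both potential outcomes $Y^1, Y^0$ (coupled through a shared
   uniform) and assembles $Y = A Y^1 + (1 - A) Y^0$.

Only `W` of the source ever enters this module — the source's real `A` and
`Y` are unread, which is the operational meaning of outcome blindness, and
the test suite verifies that scrambling the source treatment and outcome
leaves every replicate bit-identical.

Intercepts are calibrated once against the source covariate pool (not per
replicate), fixing the marginal design across replicates: the treatment
intercept pins the pool-average treatment probability, then the outcome
intercept pins the pool-average *marginal* event rate mixing the two
potential-outcome probabilities by the calibrated treatment probabilities.
Because replicates are bootstrapped from the pool, the true risk
difference is computed exactly as the pool mean of
$\text{expit}(\alpha_Y + \beta_A + c'w) - \text{expit}(\alpha_Y + c'w)$
(`true_effect()`); Monte Carlo subsampling is used only if explicitly
requested with fewer draws than pool rows.

Where the injected "subset of variables" is not dictated by the study,
`auto_design()` picks the most prevalent binary covariates and assigns
alternating-sign coefficients of user-chosen magnitude — reproducible, with
controllable confounding strength. Replicate counts and sizes are not
prescribed anywhere upstream; the package's declared desk scale is
2,000 subjects per replicate, with 500 replicates for coverage studies and
200 for model-comparison studies (and 20 at n = 1,500 in the illustrative
`analysis/` drivers).

## The eight propensity-score models

All treatment models are $L_1$-penalized logistic regressions fitted with
`glmnet`; the differences are in how covariates are weighted and how the
regularization strength $\lambda$ is chosen.

| Model | Penalty weights | $\lambda$ selection | Cross-fitting |
|-------|-----------------|---------------------|---------------|
| 1 | all 1 | CV treatment deviance | no |
| 2 | 0 on outcome-Lasso active set | CV treatment deviance | no |
| 3 | all 1 | collaborative loss | no |
| 4 | 0 on outcome-Lasso active set | collaborative loss | no |
| 5–8 | as 1–4 | as 1–4, within training folds | 5 folds |

*Model 2 (outcome-adaptive Lasso)*: a cross-validated Lasso of `Y` on `W`
over complete cases defines the outcome active set; those columns enter
the treatment model with penalization weight zero (forced in), all others
with weight one.

*Models 3–4 (collaborative-controlled)*: the upstream description of the
collaborative criterion is a bias–variance tradeoff in the estimated
treatment effect; the concrete loss implemented here — declared so it can
be swapped — is the V-fold cross-validated negative log-likelihood of the
*fluctuated* outcome regression: for each $\lambda$ on the path, the
candidate scores define the clever covariate, the one-parameter TMLE
fluctuation of a fixed initial outcome regression is fitted on training
folds, and the validation-fold binomial log-likelihood of the updated
regression is recorded (`collab_select_lambda()`). Exact ties go to the
largest (most regularized) $\lambda$ — parsimony under equal loss. Models
3 and 4 scan the same path family as Models 1 and 2 (a shared path is
assumed; both are configurable).

*Models 5–8 (cross-fitting)*: subjects are partitioned into arm-stratified
folds; each subject's score comes from the base fitter trained without
that subject's fold. The base fitter is run *wholly* within training folds
— including its $\lambda$ selection and, for Models 7–8, its initial
outcome regression — resolving the open question of whether the
collaborative loss itself is cross-fitted in favor of strict
training-fold containment.

All models emit scores truncated to `[bound, 1 - bound]` (default 0.01 —
a rare-outcome, high-dimensional setting warrants a conservative
positivity guard).

## TMLE

The initial outcome regression is a cross-validated Lasso of `Y` on
`(A, W)` with `A` unpenalized (rare-event shrinkage would otherwise drop
the treatment term). The targeting step is the one-parameter logistic
fluctuation with the signed clever covariate
$H(A, W) = A / g(W) - (1 - A) / (1 - g(W))$, fitted by Newton–Raphson to a
score tolerance of $10^{-10}$ (an error is raised if the score residual
exceeds $10^{-8}$). The estimate is the plug-in mean of
$Q^*(1, W) - Q^*(0, W)$; the standard error is the sample SD of the
estimated efficient influence function over $\sqrt n$, with a 95% Wald
interval. Initial predictions are bounded into $[10^{-6}, 1 - 10^{-6}]$
before the logit for numerical safety.

## Model comparison and selection

`compare_models()` runs each model's full pipeline per replicate and
summarizes bias, MSE, and closed-interval coverage against the design's
true effect. Ranking is by $|\text{bias}|$, ties by MSE, then by lower
model id; a model failing on more than 10% of replicates is flagged and
excluded (rare-event replicates can degenerate). The initial outcome
regression is shared across models within a replicate — it does not depend
on the propensity model — both for comparability and economy.

## Sensitivity analysis and the G-value

A causal gap $\delta$ (the discrepancy between statistical and causal
parameters under violated assumptions) shifts the estimate and both
confidence bounds additively. `sensitivity_curve()` tabulates these shifts
over a grid, expressing gaps also in effect-size units (gap divided by the
outcome-scale SD, $\sqrt{\bar p (1 - \bar p)}$ for a binary outcome) and
adjustment units (gap divided by |unadjusted − adjusted|). Both
denominators are declared stand-ins: the upstream axes name the units
without formulas. The G-value — the minimal gap magnitude that flips the
interval's two-sided classification against the null at $\alpha = 0.05$ —
has the closed form $\min(|L|, |U|)$, verified in the tests against a
grid-search oracle.

## Numerical choices

* **Lambda paths.** Treatment models: 100 values spanning four decades
  below the data-derived maximum. Outcome models: 30 values spanning
  $[0.05\,\lambda_{\max}, \lambda_{\max}]$ — with ~4% event rates the deep
  end of the path approaches separation (glmnet iterates to its cap and
  the fits are never selected), so the outcome path is kept shallow.
* **Cross-validation.** 10 folds for $\lambda$ selection, 5 folds for
  cross-fitting and for the collaborative loss, all arm- or
  event-stratified with seeded fold assignment; the designed comparison
  studies use 5-fold $\lambda$ selection and a coordinate-descent
  threshold of $10^{-4}$ (default $10^{-5}$) as their declared settings.
* **Sparse matrices.** Covariate blocks are handed to glmnet as sparse
  `dgCMatrix`; with claims-like prevalences this is roughly an order of
  magnitude faster with identical numerics.
* **Determinism.** A single seed fans out through `derive_seed()` (a
  31-ary string hash modulo $2^{31} - 1$) to stages, replicates, and
  folds; every artifact is byte-reproducible from the configuration.
* **Degenerate inputs.** Single-arm data, single-class outcomes, fully
  censored cohorts, empty bootstrap sources, and coefficient maps naming
  absent columns raise immediate, named errors.

## Known limitations

* The collaborative loss is one defensible concretization of
  collaborative targeted learning over a Lasso path; greedy
  covariate-by-covariate collaborative TMLE is out of scope.
* Influence-curve standard errors ignore the data-adaptive nature of the
  nuisance fits; cross-fitting (Models 5–8) mitigates but does not remove
  this.
* The bias ordering of the cross-fitted collaborative models over the
  plain CV Lasso is a property of the designed confounding scenario at
  fixed seeds; it is directional evidence, not a theorem, and
  seed-dependent in small studies.
* Per-protocol estimands, informative censoring, and negative-control
  calibration of plausible gap sizes are deliberately not implemented.
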