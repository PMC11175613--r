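---
title: "Evaluating Brain Age as a biomarker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Brain Age as a biomarker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `cognage`, the
assumptions behind it, the defaults and why they were chosen, and what the
synthetic cohort can and cannot tell you about real data.

## 1. The question and the estimands

Brain Age is the prediction of a model trained to map brain features to
chronological age, evaluated on held-out individuals. Its appeal as a
biomarker rests on the idea that the *discrepancy* between predicted and
actual age carries clinical information. `cognage` operationalises the
evaluation of that idea for one phenotype — a fluid-cognition composite
score — through three estimands:

1. **Predictive performance** of each model (Pearson r, sum-of-squares R²,
   MAE) on pooled out-of-fold predictions.
2. **Simple-regression R²** of each Brain Age index, and of Brain
   Cognition, as the sole explanation of fluid cognition.
3. **Commonality components**: how the R² of a multiple regression on
   {age, index} or {age, index, Brain Cognition} splits into unique and
   shared parts.

The central diagnostic is the dissociation between (1) and (3): a model can
be excellent at predicting age while its index contributes almost nothing
*beyond* age, precisely because good age prediction makes the index
collinear with age.

## 2. Prediction machinery

### Nested cross-validation

Participants are split into five outer folds (sizes within one of each
other). Each outer-training set is split into five inner folds twice,
independently: once for tuning the per-feature-set models, once for tuning
the stacked models. All tuning, preprocessing and bias-correction
parameters are functions of training rows only; the test fold enters only
at evaluation. The no-leakage contract is enforced by tests that perturb
test rows and require bit-identical fitted objects.

### Elastic Net and its tuning

The solver minimises
`||y − Xβ||²/(2n) + α·l1·||β||₁ + ½·α·(1−l1)·||β||₂²` with an unpenalised
intercept on already-standardised features. Fitting is delegated to
`glmnet`; because `glmnet` parameterises its penalty on the scale of the
response standardised by its 1/n standard deviation, the package maps
`(α, l1)` to `lambda = α·(l1 + (1−l1)·sd_n(y))` and
`alpha = l1/(l1 + (1−l1)·sd_n(y))`. The mapping is verified in the test
suite against the closed-form ridge solution, ordinary least squares in the
vanishing-penalty limit, and an independent coordinate-descent oracle.
Single-column designs (which arise in one-member stacks) use the exact
univariate soft-threshold solution.

The default grid is 70 α values log10-spaced on [0.1, 100] × 25 l1 values
on [0, 1]. Grid search maximises mean inner-validation R² (sum-of-squares
form); ties break to the first point in ascending (α, l1) order, which
makes selection deterministic. For each inner fold the full α path for one
l1 value is fitted in a single call, which keeps even the full grid
tractable. A 7×5 `reduced_grid()` is used in examples and tests.

Two resolved design questions: preprocessing during grid search is re-fit
per inner fold (the stricter anti-leakage reading), and stacking features
are the level-1 models' in-sample predictions on the outer-training rows,
matching the three-step tuning description the pipeline implements; an
out-of-sample stacking variant was considered and deliberately not made the
default, since the second-stage inner CV already guards against overfit
stack weights.

### Preprocessing order

For connectivity-like sets the order is: PCA (fit on training rows,
components by decreasing variance, sign fixed so each loading vector's
largest-magnitude entry is positive), then sex residualisation, then
standardisation of the component scores. The relative order of PCA and sex
residualisation is genuinely ambiguous in practice; `sex_before_pca = TRUE`
switches to residualising the raw edges first. Zero-variance features are
dropped with a warning rather than producing division errors; a requested
component count above the available rank is reduced with a warning.

### Stacked models

Eight canonical stacks are resolved from modality tags (`task_contrast`,
`task_fc`, `rest_fc`, `smri`). Stacking designs are standardised but not
sex-residualised: sex was already removed from the brain features at level
1, and the stacking inputs are predictions, not brain measurements.

## 3. Brain Age indices

The bias line `ŷ = β₀ + β₁·a` is fitted per outer fold on the refitted
model's in-sample training predictions, and applied to that fold's test
predictions. Two exact identities are enforced by tests: within the
training fold, regressing corrected predictions on age returns slope 1 and
intercept 0 (to 1e−8); and both gap columns equal their defining
differences row-wise. A slope below 1e−6 in magnitude (a constant
predictor) raises an error — the correction is undefined there, and
silently passing NaNs downstream would be worse.

## 4. Commonality analysis

All R² values here are in-sample OLS R² on the pooled out-of-fold table:
these are explanatory decompositions, not predictions. For two blocks,
unique effects are `R²_full − R²_other` and the common effect is
`R²₁ + R²₂ − R²_full`; the three-block closed forms follow the same
inclusion–exclusion pattern, and the implementation is tested to agree with
a generic all-subsets oracle to 1e−10. Components always sum to the full
R² before rescaling. Negative common effects — a known artefact of
multicollinearity — are zeroed and the remaining components rescaled
proportionally to preserve the total, flagged by `rescaled`.

Significance of unique effects uses the hierarchical F test at an
uncorrected 0.05 threshold; no multiplicity correction is applied, so the
`significant` flags should be read descriptively.

Two robustness variants: (a) a ridge engine, whose penalty is chosen once
by 5-fold CV on the full model and reused for every subset (selecting per
subset would make the subset R²s incomparable); (b) a quadratic-age
variant, where `{age, age²}` is treated as a single block so that the
"chronological age" components keep their meaning.

## 5. The synthetic cohort

### Generative model

Ages are uniform on the specified range (a uniform keeps signal across the
range; the optional `recode_90plus` flag reproduces the privacy recoding of
ages above 90 to 100 but is off by default because it is an artefact, not
structure). Sex is Bernoulli. A standardised age score `z`, an
age-independent distortion `w`, and a brain latent `g` generate:

- a shared brain-aging latent `u = √ρ·z + √(1−ρ)·w`, so that *no*
  combination of brain features can explain more than ρ of the variance in
  age (`age_latent_ceiling`, default 0.78 — chosen so that a many-set
  stacked model plateaus near the high-0.7s rather than unrealistically
  approaching 1);
- fluid cognition `= 100 + 15·(−√A·z + √B·g + √(1−A−B)·ε)` with
  `A = cognition_age_share` (default 0.32) and
  `B = cognition_brain_share` (default 0.15), negative age loading by
  convention;
- per set s, an age-bearing latent `t_s` (population R² of age on the set
  equals `age_signal_share[s]`) and a cognition-bearing latent `q_s`
  carrying `cognition_signal_share[s]` of `g`; features load on `t_s` with
  weight √0.55, on `q_s` with weight √0.30 and alternating sign (so the two
  set latents remain separable), carry √0.15 unique noise, and receive an
  additive `sex_effect_size` shift (default 0.2 SD).

### Closed-form ground truth

`ground_truth_r2()` computes the *exact* finite-dimension population R² of
age and of cognition on each complete feature set from the factor
covariance (via the Woodbury identity, so 71,631-column sets cost nothing),
not just the asymptotic shares. Tests at n = 10⁵ recover these values
within 0.01, and the nested-CV engine at n = 500 recovers them within 0.1.

### What passing tests do and do not show

The generator emulates: heterogeneous set dimensionality, a shared and
bounded age signal, partially overlapping age/cognition variance, additive
sex effects, and the negative age–cognition association. It does **not**
emulate: non-linear age trajectories, heteroscedastic or heavy-tailed
features, site/motion artefacts, missingness, or realistic connectivity
geometry (connectivity sets are generated directly as wide matrices — the
pipeline consumes post-correlation features, so nothing upstream of the
correlation table is simulated). Passing recovery tests therefore
demonstrates the *pipeline's* correctness under its stated assumptions, not
that real cohorts satisfy those assumptions.

## 6. Numerical choices and degenerate inputs

- glmnet convergence threshold 1e−8 during grid search, 1e−12 for final
  fits; a short warm-start path down to the target penalty improves
  accuracy at tight tolerances.
- R² may be negative on test folds and is reported unclipped; a constant
  prediction vector yields an undefined Pearson r, reported `NA`.
- `fisher_z` rejects |r| ≥ 1; `vectorize_offdiagonal` requires symmetry to
  1e−8 and documents row-major upper-triangle order (1,2), (1,3), …
- All randomness flows through explicit integer seeds
  (`withr::with_seed`), giving bit-identical reruns of any configuration.

## 7. Problem sizes in examples and tests

The demonstrations in this package run cohorts of 60–500 participants,
three to four feature sets (with a full 18-set registry exercised at
minimal dimensionality to verify the 26-model count), the reduced 7×5 grid,
and 10–20 PCA components; these sizes were chosen so a complete run
finishes in seconds to a few minutes on a single CPU while leaving every
statistical contract testable. A full-scale analysis (18 real-sized sets,
70×25 grid, 75 components) uses the same code paths and is configured by
`hcpa_like_spec()` + `grid = "full"`.

## 8. Known limitations

- The bias-correction line is fitted on in-sample training predictions of
  the refitted tuned model; if a model badly overfits its training fold,
  the corrected index inherits that optimism (the alternative — inner-CV
  predictions — is not what the three-step scheme produces).
- Commonality components are descriptive decompositions; they carry no
  causal interpretation, and the rescaling of negative commons is a
  reporting convention, not an estimator.
- With fewer than four modality tags some of the eight default stacks
  coincide; they are still fitted independently (and may tie exactly),
  which mirrors how the registry is defined rather than deduplicating it.
- The generator's linear-Gaussian choice is the package's own; no
  distributional detail of real feature sets informed it.
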