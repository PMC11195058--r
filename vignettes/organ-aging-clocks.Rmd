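---
title: "Methods: organ-specific plasma proteomic aging clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-specific plasma proteomic aging clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements,
the parameters that matter, the synthetic data it validates against, and
the design decisions taken where the method left genuine freedom.

## The model

For each organ *o* we observe a panel of plasma proteins whose encoding
genes are expressed at least four-fold higher in *o* than in any other
organ of a bulk tissue expression atlas. A sparse linear clock

$$\hat a_i = w^\top x_i + b$$

is fitted by LASSO to predict chronological age $a_i$ from the panel's
standardized protein levels $x_i$. The **age gap** is the residual of a
linear regression of $\hat a$ on $a$ fitted on the training samples,

$$g_i = \hat a_i - (\alpha + \beta a_i),$$

and the **z-gap** standardizes $g$ by the training gap mean and SD. By
construction training z-gaps have mean 0 and SD 1 and are orthogonal to
age, so a z-gap is interpretable as "SDs older/younger than peers of the
same chronological age". The downstream statistics — per-SD Cox hazard
ratios, extreme-ager taxonomy at |z| ≥ 1.5, 0.5-SD gap bins, Gini
dispersion of per-organ log hazard ratios, FIBA permutation importance —
are all defined on z-gaps.

Key assumptions: protein levels depend (approximately linearly) on both
chronological age and organ-level biological aging; the cross-sectional
residual of an age prediction isolates the latter; hazards are
proportional in the z-gaps; censoring is non-informative.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| enrichment fold | 4 | ratio | the organ-specificity rule; inclusive (≥) |
| missingness threshold | 0.10 | fraction | proteins removed only when *strictly* over |
| imputation neighbours k | round(√n_train) | samples | 21,504 training samples give k = 147 |
| CV folds | 5 | — | penalty selection |
| performance fraction | 0.95 (0.90 distilled) | of best mean CV R² | sparsity/performance trade-off |
| extreme-ager threshold | 1.5 | z-gap SD | inclusive comparison, configurable |
| multi-organ bins | 2–4, 5–7, 8+ | organ count | shared between aged and youthful directions |
| distillation retention | r ≥ 0.8 | correlation | held-out fidelity to the parent clock |
| FIBA permutations | 10 | — | per-protein; permuted-effect SD always reported |
| BH scope | per analysis family | — | q-values computed within each grid |

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis assumes:

- **Ages** uniform on 40–70 years (recruitment-age range; the uniform
  shape maximizes design spread for clock training — the real cohort's
  age histogram is not reproduced).
- **Latent gaps**: one factor per organ plus an *organismal* shared
  factor, drawn from an equicorrelated multivariate normal with pairwise
  ρ = 0.21, matching the reported mean pairwise gap correlation with the
  simplest structure; a full correlation matrix can be supplied instead.
  Including the organismal factor in the same correlation structure gives
  the ~13 mildly correlated clock models the analysis works with.
- **Longitudinal visits**: a stationary AR(1) on each factor with
  persistence 0.6, visits spaced N(9.1, 1.8²) then N(3.3, 1.6²) years
  apart (truncated at 0.5 years to keep visits ordered).
- **Proteome emission**: protein *j* in organ *o*'s panel is
  $a_j\,\text{age} + b_j\,g_o + s_j\,\text{male} + \varepsilon$ with
  $\varepsilon \sim N(0, 1)$ by default. The gap loading is coupled to the
  age slope, $b_j = a_j \cdot \kappa$ with κ = 10 years/SD: a latent gap
  acts as extra biological years, shifting each protein along its own age
  trajectory. This coupling is what makes age-trained clocks carry gap
  signal at all — with independently signed loadings the LASSO's
  age-aligned weights would cancel the gap term, which is neither how
  biological age is conceptualized nor how the real clocks behave.
  κ = 0 gives the null-signal design used in tests.
- **Events**: inverse-transform sampling from a proportional-hazards model
  with constant (exponential) baseline hazard, log-linear effects of the
  baseline latent gaps, age (centred at 55) and sex, and administrative
  censoring at 17 years. The exponential baseline is a deliberate choice:
  it has closed forms for every oracle test (mean event time, survival
  probability-integral transform) while leaving the Cox estimand
  untouched. Default mortality effects (brain HR 1.25, other organs 1.10
  per SD, jointly) produce marginal per-SD hazard ratios in the reported
  20–60 % band under the gap correlation.
- **Centres** assigned uniformly; **missingness** MCAR, matching the
  assumption under which KNN imputation is being tested.

What it does *not* emulate: assay normalization internals, plate/batch
and centre effects on protein levels, limits of detection, informative
missingness, non-proportional hazards, competing risks, or the empirical
ageotype prevalences (which depend on the real cohort's full correlation
matrix). Passing recovery tests therefore validates the estimators under
the model's assumptions, not the assumptions themselves.

## Numerical choices and degenerate inputs

- **"Performance" in the 95 %/90 % rule** is the mean cross-validated R²,
  computed as 1 − CV-MSE / Var(age); among qualifying penalties the
  largest (sparsest) is chosen, matching the rule's purpose of deriving
  sparse models. The penalty path is glmnet's 100-value log-spaced path
  auto-scaled from the data; CV folds are seeded.
- A clock whose best CV R² is ≤ 0 is **flagged non-predictive** and its
  gap computation is disabled rather than silently emitted.
- **Residualizer and z-scale are training-anchored** and applied
  everywhere, keeping test gaps honestly out-of-sample; the residualizer
  is rejected if training age variance is zero.
- **Enrichment edge cases**: a gene positive in exactly one organ and zero
  elsewhere is enriched there (the ratio is infinite); an all-zero gene is
  unassigned; an exact expression tie can never satisfy a fold > 1.
  Max-expression cell-type labels treat exact ties as unassigned with a
  tie flag.
- **KNN imputation** uses nan-Euclidean distances (mean squared difference
  over co-observed proteins rescaled by the total protein count), donors
  restricted to training samples with the target protein observed, and
  falls back to the training column mean when no donor exists. Missing
  fractions are computed on the combined matrix before splitting, since
  the protein-removal count is reported globally.
- **Gap bins** are left-closed right-open with unbounded outer bins, so
  z = 1.5 falls in the top bin, consistent with the inclusive extreme
  threshold.
- **Cox models** use the Efron tie approximation; degenerate endpoints
  (< 2 events or non-convergence) are flagged, never estimated. Time since
  blood draw is the timescale with age at draw as a covariate.
- **Gini clipping**: negative log hazard ratios are clipped to 0 before
  the Gini, which is ill-defined for mixed signs; an all-zero clipped
  vector is flagged undefined. The statistic is scale-invariant and lies
  in [0, 1).
- **BH correction** delegates to `stats::p.adjust("BH")`. The q-values
  are monotone in p, ≥ p, and capped at 1; note that re-applying BH to
  q-values is *not* an identity in general, so no code relies on it.
- **Distillation** targets the parent clock's predicted age, selects its
  penalty by the 90 % rule, then runs backward feature elimination ranked
  by |coefficient| with 5-fold CV, keeping the smallest subset within
  10⁻³ of the best CV R² and refitting it by OLS. The retention rule is
  read on the correlation scale (r ≥ 0.8, configurable), the stricter of
  the two plausible readings (r vs r²), and the threshold used is
  recorded.
- **FIBA** permutes the analysis-ready (imputed, scaled) column so only
  the clock's use of a protein is ablated, freezes the residualizer and
  z-scale, and scores baseline minus mean permuted effect over seeded
  permutations; failed permutation refits are dropped and counted. A
  useful caveat shown by the tests: the score is informative when the gap
  is a *noisy* readout of the latent driver (the realistic regime); for a
  nearly noise-free gap, per-unit attenuation effects can compress scores.
- **Pipeline reproducibility**: one global seed fans out to per-stage
  seeds by a fixed affine derivation; the manifest records config hash,
  settings in force, counts at each filtering step, and md5 digests of
  every artifact, enabling resume-from-last-valid-stage reruns.

## Problem sizes used by the test suite

The suite validates distributional properties at n = 20,000 subjects
(gap correlation, persistence, extreme rates), planted-effect recovery at
n = 5,000–10,000 (per-SD HR 1.8 within [1.65, 1.96]; linear effect 0.3
within ±0.03), clock behaviour at n = 3,000–5,000 with 20 proteins per
organ, null calibration over 400 endpoint–organ pairs, and exact oracle
arithmetic on 4–6-record toys. These sizes were chosen so each property's
sampling error is small relative to its tolerance.

## Known limitations

- Organ panels inherit whatever tissue-aggregation and annotation choices
  the supplied atlas embodies; the enrichment caller applies no expression
  floor beyond the fold rule (any additional filters are left to the
  caller).
- Clocks are protein-only; sex is a downstream covariate, not a feature.
- The per-SD hazard ratio of an estimated z-gap is attenuated relative to
  the latent gap's effect by the clock's estimation noise; recovery tests
  on estimated gaps therefore bound, rather than equal, the planted
  values unless the latent gap itself is used as the exposure.
- No proportional-hazards diagnostics are included, and gene-ontology
  enrichment, ICD-code grouping, and image processing are out of scope;
  their outputs enter only as generic covariates or pre-grouped events.
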