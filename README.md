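# organclock

Organ-specific biological age from plasma proteomics.

People's organs age at different rates, and the plasma proteome carries
organ-derived signals of that process. `organclock` implements the full
analysis used to turn a samples × proteins abundance matrix into
**organ-specific biological age estimates** and their downstream
epidemiology:

1. **Organ panels.** A gene is *organ-enriched* when its expression in one
   organ of a tissue atlas is at least four-fold higher than in any other
   organ; the plasma proteins encoded by those genes form each organ's
   panel. Proteins enriched nowhere form the *organismal* panel, and the
   whole assay forms the *conventional* panel.
2. **Clocks.** Per panel, a LASSO regression predicts chronological age
   from protein levels. The penalty is chosen by 5-fold cross-validation as
   the **largest penalty retaining ≥ 95 % of the best mean CV R²** (90 %
   for distilled reduced-platform clocks), which keeps models sparse.
   Preprocessing is centre-held-out: samples are split train/test by
   collection centre, proteins missing in > 10 % of samples are dropped,
   the rest are KNN-imputed with k = √n_train neighbours, and z-scored with
   training means/SDs.
3. **Age gaps.** The *age gap* is the residual of predicted age regressed
   on actual age (fitted on training samples); gaps are z-scored per model.
   A z-gap of +1 means the organ looks one population-SD older than peers
   of the same chronological age.
4. **Ageotypes.** Samples with any |z-gap| ≥ 1.5 are extreme agers:
   single-organ, multi-organ (2–4 / 5–7 / 8+ organs, aged or youthful), or
   ambiguous (both signs). Gap bins of 0.5 SD support longitudinal
   transition analysis.
5. **Associations.** Cox proportional-hazards models (age- and
   sex-adjusted, Efron ties) give per-SD hazard ratios of gaps for disease
   and mortality; linear models cover lifestyle/progression analyses;
   Benjamini–Hochberg correction controls the FDR; the **Gini coefficient
   of per-organ log hazard ratios** separates organ-specific from systemic
   diseases; penalized Cox models compare mortality-predictor sets by
   concordance; Kaplan–Meier curves summarize group survival.
6. **FIBA** (permutation Feature Importance for Biological Aging): a clock
   protein's importance for an outcome is the effect-size loss after
   permuting its column and recomputing gaps with the frozen clock.

Because the cohort data such analyses are built on are access-restricted,
the package ships a **synthetic cohort generator** that emulates the
analysis' statistical structure — equicorrelated latent organ age gaps
(mean pairwise r ≈ 0.21), AR(1) longitudinal persistence (r ≈ 0.6), a
linear proteome emission model, proportional-hazards events with
administrative censoring at 17 years, collection centres, and MCAR
missingness — with full ground truth, so every stage is testable by
parameter recovery.

## Worked example

```r
library(organclock)

cfg   <- simulation_config(n_subjects = 2000, seed = 101, missing_rate = 0.01)
ch    <- generate_cohort(cfg)
split <- split_by_center(data.frame(sample_id = ch$subjects$subject_id,
                                    center    = ch$subjects$center),
                         sort(unique(ch$subjects$center))[1:10])
pp    <- preprocess(ch$proteome[[1]], split)          # filter -> impute -> scale
age   <- setNames(ch$visits$age[ch$visits$visit == 1], ch$subjects$subject_id)

ld    <- ch$truth$loadings
brain <- fit_clock(pp$train, age[rownames(pp$train)],
                   panel = intersect(ld$protein[ld$organ == "brain"],
                                     colnames(pp$train)),
                   name = "brain", seed = 1)
brain
#> <clock_model 'brain'> 10/10 nonzero proteins; lambda=0.5336; predictive

gaps <- compute_age_gaps(brain, predict_age(brain, pp$test),
                         age[rownames(pp$test)])
cor(gaps$z_gap, gap_matrix(ch)[rownames(pp$test), "brain"])
#> [1] 0.79          # held-out recovery of the latent brain age gap

idx <- match(gaps$sample_id, ch$subjects$subject_id)
rec <- data.frame(time = ch$events$mortality$time[idx],
                  status = ch$events$mortality$status[idx],
                  age = unname(age[gaps$sample_id]), sex = ch$subjects$sex[idx])
cox_association(gaps$z_gap, rec, name = "brain")[, c("hr", "ci_low", "ci_high", "p")]
#>       hr ci_low ci_high      p
#> 1 1.2763 1.0767  1.5128 0.0049   # per-SD mortality HR, 121 events / 1047
```

The estimated brain clock recovers the planted latent gap at r = 0.79 on
held-out centres, and one SD of estimated brain aging carries a 1.28-fold
mortality hazard (the planted effect, attenuated by the clock's estimation
noise) — the same qualitative picture as the study design the package
implements.

`run_pipeline(cfg, "out/")` chains all stages (simulate → panels →
preprocess → clocks → gaps → ageotypes → associations → optional FIBA),
persists plain-text artifacts, and writes a digest-stamped `manifest.json`
that makes deterministic stages bit-reproducible and resumable.

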