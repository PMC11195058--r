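#' Permutation feature importance for biological aging (FIBA)
#'
#' Quantifies each clock protein's contribution to the age gap's association
#' with an outcome. For every nonzero-weight protein, its (analysis-ready)
#' column is permuted across samples `n_perm` times; ages, gaps and z-gaps
#' are recomputed with the clock's frozen weights, residualizer and z-scale
#' (nothing is refitted), the outcome association is refitted, and the FIBA
#' score is the baseline effect size minus the mean permuted effect size.
#' Proteins the clock does not use score exactly 0 without computation.
#'
#' @param clock A predictive `clock_model`.
#' @param x Analysis-ready (imputed, scaled) samples x proteins matrix.
#' @param records Outcome records aligned with rows of `x`: `time` + `status`
#'   for `outcome = "cox"`, or an `outcome` column for `outcome = "linear"`,
#'   plus covariate columns.
#' @param outcome `"cox"` (effect = per-SD log HR) or `"linear"` (slope).
#' @param covariates Covariate columns in `records` (default age, sex).
#' @param n_perm Permutations per protein (default 10).
#' @param seed Seed for the permutation streams.
#' @return Object of class `fiba_result`: data frame `protein`, `weight`,
#'   `score`, `baseline`, `perm_mean`, `perm_sd`, `n_ok`, `flagged`, with
#'   attributes `baseline`, `effect_measure`, `n_perm`, `seed`.
#' @export
fiba_scores <- function(clock, x, records, outcome = c("cox", "linear"),
                        covariates = c("age", "sex"), n_perm = 10, seed = 1) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(clock, "clock_model"), is.matrix(x),
            nrow(x) == nrow(records))
  if (!clock$predictive) stop("clock is flagged non-predictive")
  if (!("age" %in% names(records)))
    stop("records must carry the chronological age column 'age'")

  effect_of <- function(mat) {
    pred <- predict_age(clock, mat)
    zg <- compute_age_gaps(clock, pred, records$age)$z_gap
    if (outcome == "cox") {
      row <- cox_association(zg, records, covariates = covariates)
      if (row$flagged[1]) NA_real_ else row$estimate[1]
    } else {
      row <- linear_association(records$outcome, zg,
                                covariates = records[, covariates, drop = FALSE])
      row$estimate[1]
    }
  }

  baseline <- effect_of(x)
  if (!is.finite(baseline)) stop("baseline outcome association failed")
  active <- names(clock$weights)[clock$weights != 0]
  zero_w <- setdiff(clock$panel, active)

  rows <- lapply(seq_along(active), function(pi) {
    p <- active[pi]
    effs <- with_seed(derive_seed(seed, pi), {
      vapply(seq_len(n_perm), function(r) {
        xp <- x
        xp[, p] <- xp[sample.int(nrow(xp)), p]
        effect_of(xp)
      }, numeric(1))
    })
    ok <- is.finite(effs)
    data.frame(protein = p, weight = unname(clock$weights[p]),
               score = if (any(ok)) baseline - mean(effs[ok]) else NA_real_,
               baseline = baseline,
               perm_mean = if (any(ok)) mean(effs[ok]) else NA_real_,
               perm_sd = if (sum(ok) > 1) stats::sd(effs[ok]) else NA_real_,
               n_ok = sum(ok), flagged = !any(ok),
               stringsAsFactors = FALSE)
  })
  zero_rows <- if (length(zero_w)) {
    data.frame(protein = zero_w, weight = 0, score = 0, baseline = baseline,
               perm_mean = baseline, perm_sd = 0, n_ok = 0L, flagged = FALSE,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(zero_rows)))
  out <- out[order(-abs(out$score)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "effect_measure") <- if (outcome == "cox") "cox log HR" else "linear slope"
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("fiba_result", class(out))
  out
}

#' Association effect after permuting every clock protein at once
#'
#' Diagnostic companion to [fiba_scores()]: permuting all used proteins
#' simultaneously should drive the recomputed gap's association to null.
#'
#' @inheritParams fiba_scores
#' @return Data frame with the refitted association row (estimate, se, ...).
#' @export
fiba_null_effect <- function(clock, x, records, outcome = c("cox", "linear"),
                             covariates = c("age", "sex"), seed = 1) {
  outcome <- match.arg(outcome)
  active <- names(clock$weights)[clock$weights != 0]
  xp <- with_seed(seed, {
    for (p in active) x[, p] <- x[sample.int(nrow(x)), p]
    x
  })
  pred <- predict_age(clock, xp)
  zg <- compute_age_gaps(clock, pred, records$age)$z_gap
  if (outcome == "cox") cox_association(zg, records, covariates = covariates)
  else linear_association(records$outcome, zg,
                          covariates = records[, covariates, drop = FALSE])
}
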