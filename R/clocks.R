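#' Construct a clock model directly
#'
#' Low-level constructor for a sparse linear aging model; [fit_clock()] is
#' the usual entry point. Useful for importing published coefficients or for
#' building fully specified toy clocks.
#'
#' @param name Model name.
#' @param weights Named numeric vector of protein weights (zeros allowed).
#' @param intercept Model intercept (years).
#' @param residualizer Numeric `c(intercept, slope)` of the predicted-vs-actual
#'   age regression fitted on training samples.
#' @param gap_mean,gap_sd Training age-gap mean and SD (SD must be > 0).
#' @param panel Protein panel the clock was trained on.
#' @param predictive Logical; `FALSE` flags a non-predictive clock whose gaps
#'   are disabled.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, weights, intercept,
                        residualizer = c(0, 1), gap_mean = 0, gap_sd = 1,
                        panel = names(weights), predictive = TRUE) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            length(residualizer) == 2)
  if (gap_sd <= 0) stop("gap scale SD must be > 0")
  structure(list(name = name, weights = weights, intercept = intercept,
                 residualizer = as.numeric(residualizer),
                 gap_mean = gap_mean, gap_sd = gap_sd,
                 panel = panel, predictive = predictive,
                 lambda = NA_real_, cv_record = NULL),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("<clock_model '%s'> %d/%d nonzero proteins; lambda=%.4g; %s\n",
              x$name, nz, length(x$panel), x$lambda,
              if (x$predictive) "predictive" else "flagged non-predictive"))
  invisible(x)
}

#' Train a sparse penalized age clock
#'
#' Fits a LASSO path for chronological age on the panel's proteins with
#' 5-fold cross-validation; performance per penalty is the mean
#' cross-validated R-squared. The chosen penalty is the largest (sparsest)
#' whose performance is at least `perf_fraction` of the best, and the final
#' model is the path fit on all training samples at that penalty. The
#' residualizer (predicted age regressed on actual age) and the age-gap
#' z-scale are fitted on the training predictions.
#'
#' @param x Standardized training matrix (samples x proteins).
#' @param age Chronological ages (years) of the training samples.
#' @param panel Character vector of panel proteins (columns of `x`).
#' @param name Model name.
#' @param perf_fraction Fraction of best CV performance required (default
#'   0.95; the distilled models use 0.90).
#' @param nfolds Cross-validation folds (5).
#' @param seed Seed for the CV fold assignment.
#' @return A `clock_model` with cross-validation record (`lambda`, `cv_r2`,
#'   `nonzero`), training-set correlation `train_r`, and gap parameters. If
#'   the best CV R-squared is <= 0 the model is flagged non-predictive and
#'   gap computation is disabled.
#' @export
fit_clock <- function(x, age, panel = colnames(x), name = "clock",
                      perf_fraction = 0.95, nfolds = 5, seed = 1) {
  stopifnot(is.matrix(x), length(age) == nrow(x))
  if (nrow(x) < 10) stop("need at least 10 training samples")
  if (!(perf_fraction > 0 && perf_fraction <= 1))
    stop("perf_fraction must be in (0, 1]")
  missing_p <- setdiff(panel, colnames(x))
  if (length(missing_p))
    stop("panel protein(s) absent from matrix: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  xm <- x[, panel, drop = FALSE]
  if (ncol(xm) < 2) {
    # glmnet needs >= 2 columns; duplicate-free single-protein panels are
    # handled as a plain degree-1 fit on the lasso's behalf
    xm <- cbind(xm, `.null.` = 0)
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(xm))))
  cv <- glmnet::cv.glmnet(xm, age, foldid = foldid, family = "gaussian",
                          type.measure = "mse", standardize = TRUE)
  var_y <- mean((age - mean(age))^2)
  cv_r2 <- 1 - cv$cvm / var_y
  record <- data.frame(lambda = cv$lambda, cv_r2 = cv_r2,
                       nonzero = cv$nzero, row.names = NULL)
  best <- max(cv_r2)
  predictive <- best > 0
  if (predictive) {
    qualifying <- which(cv_r2 >= perf_fraction * best)
    # cv$lambda is decreasing, so the first qualifying index is the largest
    sel <- qualifying[1]
  } else {
    sel <- which.max(cv_r2)
  }
  lam <- cv$lambda[sel]
  cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))[, 1]
  w <- cf[-1]
  w <- w[names(w) != ".null."]
  w <- w[w != 0]
  if (length(w) == 0) w <- stats::setNames(numeric(0), character(0))
  pred <- drop(x[, names(w), drop = FALSE] %*% w) + cf[1]

  res <- c(0, 1); gmean <- 0; gsd <- 1; train_r <- NA_real_
  if (predictive) {
    if (stats::sd(age) == 0) stop("zero age variance in training samples")
    fit <- stats::lm.fit(cbind(1, age), pred)
    res <- unname(fit$coefficients)
    gaps <- pred - (res[1] + res[2] * age)
    gmean <- mean(gaps)
    gsd <- stats::sd(gaps)
    if (!is.finite(gsd) || gsd <= 0) {
      predictive <- FALSE
      gsd <- 1
    }
    train_r <- suppressWarnings(stats::cor(pred, age))
  }
  structure(list(name = name, weights = w, intercept = unname(cf[1]),
                 residualizer = res, gap_mean = gmean, gap_sd = gsd,
                 panel = panel, predictive = predictive,
                 lambda = lam, perf_fraction = perf_fraction,
                 cv_record = record, train_r = train_r),
            class = "clock_model")
}

#' Predict age with a clock
#'
#' @param clock A `clock_model`.
#' @param x Samples x proteins matrix containing every nonzero-weight protein.
#' @return Named numeric vector of predicted ages (years).
#' @export
predict_age <- function(clock, x) {
  stopifnot(inherits(clock, "clock_model"), is.matrix(x))
  need <- names(clock$weights)[clock$weights != 0]
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stop("matrix is missing required protein(s): ", paste(miss, collapse = ", "))
  if (length(need) == 0)
    return(stats::setNames(rep(clock$intercept, nrow(x)), rownames(x)))
  w <- clock$weights[need]
  stats::setNames(drop(x[, need, drop = FALSE] %*% w) + clock$intercept,
                  rownames(x))
}

#' Compute raw and z-scored age gaps
#'
#' The raw gap is the residual of predicted age with respect to the
#' training-fitted regression of predicted on actual age; the z-gap
#' standardizes it by the training gap mean and SD. Both the residualizer and
#' the z-scale are training-anchored so test gaps are honestly out-of-sample.
#'
#' @param clock A predictive `clock_model`.
#' @param predicted Predicted ages from [predict_age()].
#' @param actual Chronological ages.
#' @param sample_id Sample identifiers (defaults to names of `predicted`).
#' @return Data frame `sample_id`, `model`, `predicted_age`, `gap`, `z_gap`.
#' @export
compute_age_gaps <- function(clock, predicted, actual,
                             sample_id = names(predicted)) {
  stopifnot(inherits(clock, "clock_model"), length(predicted) == length(actual))
  if (!clock$predictive)
    stop("clock '", clock$name, "' is flagged non-predictive; gaps disabled")
  r <- clock$residualizer
  if (!all(is.finite(r))) stop("degenerate residualizer")
  gap <- predicted - (r[1] + r[2] * actual)
  data.frame(sample_id = sample_id %||% seq_along(predicted),
             model = clock$name,
             predicted_age = unname(predicted),
             gap = unname(gap),
             z_gap = unname((gap - clock$gap_mean) / clock$gap_sd),
             stringsAsFactors = FALSE)
}

#' Age-gap table for a set of clocks
#'
#' @param clocks Named list of predictive `clock_model`s.
#' @param x Samples x proteins matrix.
#' @param age Chronological ages aligned with rows of `x`.
#' @return Long data frame of gap rows, one per (sample, model).
#' @export
age_gap_table <- function(clocks, x, age) {
  do.call(rbind, lapply(clocks, function(cl) {
    compute_age_gaps(cl, predict_age(cl, x), age)
  }))
}

#' Wide z-gap matrix from a long age-gap table
#'
#' @param gap_table Output of [age_gap_table()].
#' @return Numeric matrix samples x models of z-gaps.
#' @export
zgap_matrix <- function(gap_table) {
  models <- unique(gap_table$model)
  ids <- unique(gap_table$sample_id)
  m <- matrix(NA_real_, length(ids), length(models),
              dimnames = list(ids, models))
  m[cbind(match(gap_table$sample_id, ids), match(gap_table$model, models))] <-
    gap_table$z_gap
  m
}

#' Fit the organ-ages-to-conventional-age meta-model
#'
#' A LASSO fit of the conventional clock's predicted age on the organ and
#' organismal predicted ages; reports the variance explained and the
#' absolute-normalized relative weights.
#'
#' @param organ_ages Samples x models matrix of predicted ages (>= 2 columns).
#' @param conventional_age Conventional clock's predicted ages.
#' @param seed CV fold seed.
#' @return Object of class `meta_clock`: `weights`, `intercept`,
#'   `relative_weights` (summing to 1), `r_squared`.
#' @export
fit_meta_clock <- function(organ_ages, conventional_age, seed = 1) {
  stopifnot(is.matrix(organ_ages))
  if (ncol(organ_ages) < 2) stop("need at least 2 organ age columns")
  foldid <- with_seed(seed, sample(rep_len(1:5, nrow(organ_ages))))
  cv <- glmnet::cv.glmnet(organ_ages, conventional_age, foldid = foldid)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  w <- cf[-1]
  pred <- drop(organ_ages %*% w) + cf[1]
  r2 <- 1 - mean((conventional_age - pred)^2) /
    mean((conventional_age - mean(conventional_age))^2)
  rel <- if (sum(abs(w)) > 0) abs(w) / sum(abs(w)) else abs(w)
  structure(list(weights = w, intercept = unname(cf[1]),
                 relative_weights = rel, r_squared = r2),
            class = "meta_clock")
}

# 5-fold CV R^2 of an OLS fit of y on x[, cols]
cv_r2_ols <- function(x, y, cols, foldid) {
  pred <- rep(NA_real_, length(y))
  for (f in unique(foldid)) {
    tr <- foldid != f
    xt <- cbind(1, x[tr, cols, drop = FALSE])
    cf <- tryCatch(stats::lm.fit(xt, y[tr])$coefficients, error = function(e) NULL)
    if (is.null(cf)) return(-Inf)
    cf[is.na(cf)] <- 0
    pred[!tr] <- drop(cbind(1, x[!tr, cols, drop = FALSE]) %*% cf)
  }
  1 - mean((y - pred)^2) / mean((y - mean(y))^2)
}

#' Distill a clock onto a reduced protein platform
#'
#' Trains a LASSO model to predict the parent clock's predicted age from the
#' reduced panel (penalty chosen by the 90% rule), then recursively
#' eliminates the weakest features under 5-fold cross-validation to minimize
#' the feature count. The distilled model is retained only if its predicted
#' ages correlate with the parent's at `r >= retention_r` on the held-out
#' samples; otherwise a drop record is returned.
#'
#' @param parent The parent `clock_model` (trained on the full platform).
#' @param train_x Training matrix containing both the parent's proteins and
#'   the reduced panel.
#' @param train_age Training chronological ages (for the residualizer).
#' @param eval_x Held-out matrix for the retention check (no overlap with
#'   training samples).
#' @param eval_age Held-out chronological ages.
#' @param reduced_panel Proteins available on the reduced platform.
#' @param perf_fraction Fraction of best CV performance (default 0.90).
#' @param retention_r Minimum held-out correlation with the parent (0.8).
#' @param rfe Run recursive feature elimination (default `TRUE`).
#' @param rfe_tol CV R-squared tolerance when minimizing the feature count.
#' @param seed CV fold seed.
#' @return A retained `clock_model` (with `parent`, `parent_cor`,
#'   `retained = TRUE` fields) or a `distill_drop` record.
#' @export
distill_clock <- function(parent, train_x, train_age, eval_x, eval_age,
                          reduced_panel, perf_fraction = 0.90,
                          retention_r = 0.8, rfe = TRUE, rfe_tol = 1e-3,
                          seed = 1) {
  stopifnot(inherits(parent, "clock_model"))
  reduced_panel <- intersect(reduced_panel, colnames(train_x))
  if (length(reduced_panel) == 0) stop("reduced panel is empty")
  y <- unname(predict_age(parent, train_x))
  base <- fit_clock(train_x, y, panel = reduced_panel,
                    name = paste0(parent$name, "_distilled"),
                    perf_fraction = perf_fraction, seed = seed)
  feats <- names(base$weights)[base$weights != 0]
  xm <- train_x[, reduced_panel, drop = FALSE]
  foldid <- with_seed(seed + 1, sample(rep_len(1:5, nrow(xm))))

  if (rfe && length(feats) > 1) {
    sets <- list(feats)
    scores <- cv_r2_ols(xm, y, feats, foldid)
    cur <- feats
    while (length(cur) > 1) {
      cf <- stats::lm.fit(cbind(1, xm[, cur, drop = FALSE]), y)$coefficients[-1]
      cf[is.na(cf)] <- 0
      cur <- cur[-which.min(abs(cf))]
      sets <- c(sets, list(cur))
      scores <- c(scores, cv_r2_ols(xm, y, cur, foldid))
    }
    ok <- which(scores >= max(scores) - rfe_tol)
    feats <- sets[[ok[length(ok)]]]  # smallest qualifying feature set
  }

  # final sparse model: OLS on the selected features, target = parent ages
  cf <- stats::lm.fit(cbind(1, xm[, feats, drop = FALSE]), y)$coefficients
  cf[is.na(cf)] <- 0
  w <- stats::setNames(cf[-1], feats)
  pred_tr <- drop(xm[, feats, drop = FALSE] %*% w) + cf[1]
  rfit <- stats::lm.fit(cbind(1, train_age), pred_tr)$coefficients
  gaps <- pred_tr - (rfit[1] + rfit[2] * train_age)
  distilled <- clock_model(paste0(parent$name, "_distilled"),
                           weights = w, intercept = unname(cf[1]),
                           residualizer = unname(rfit),
                           gap_mean = mean(gaps),
                           gap_sd = max(stats::sd(gaps), 1e-12),
                           panel = reduced_panel)
  parent_eval <- unname(predict_age(parent, eval_x))
  child_eval <- unname(predict_age(distilled, eval_x))
  r <- suppressWarnings(stats::cor(parent_eval, child_eval))
  if (!is.finite(r)) r <- 0
  if (r < retention_r) {
    return(structure(list(retained = FALSE, parent = parent$name,
                          correlation = r, retention_r = retention_r,
                          n_features = length(feats)),
                     class = "distill_drop"))
  }
  distilled$parent <- parent$name
  distilled$parent_cor <- r
  distilled$retained <- TRUE
  distilled
}
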