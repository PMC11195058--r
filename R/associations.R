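#' Covariate-adjusted Cox association of an exposure with an endpoint
#'
#' Fits a Cox proportional-hazards model (Efron ties) of the endpoint on the
#' exposure plus covariates (age and sex by default). A numeric exposure that
#' is a z-scored age gap yields a per-SD hazard ratio; a factor exposure
#' (e.g. ageotype group) is contrasted against its reference level, one
#' result row per non-reference level.
#'
#' @param exposure Numeric vector or factor, aligned with `records` rows.
#' @param records Data frame with `time`, `status` and covariate columns.
#' @param covariates Covariate column names in `records` (default age, sex).
#' @param name Exposure name for the result.
#' @return Data frame of class rows: `exposure`, `model`, `estimate` (log
#'   HR), `se`, `hr`, `ci_low`, `ci_high` (HR scale), `p`, `n`, `n_events`,
#'   `flagged`.
#' @export
cox_association <- function(exposure, records, covariates = c("age", "sex"),
                            name = "exposure") {
  stopifnot(is.data.frame(records), all(c("time", "status") %in% names(records)))
  stopifnot(length(exposure) == nrow(records))
  if (any(records$time <= 0)) stop("survival times must be > 0")
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  df <- records[, c("time", "status", covariates), drop = FALSE]
  if (is.character(df$sex %||% NULL)) df$sex <- sex_indicator(df$sex)
  df$.exposure <- exposure
  n_events <- sum(records$status)
  if (n_events < 2 || length(unique(records$time[records$status == 1])) < 2) {
    return(flagged_result(name, "cox", nrow(df), n_events))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, status) ~ .exposure",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = df, ties = "efron"),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged_result(name, "cox", nrow(df), n_events))
  sm <- summary(fit)
  rows <- grep("^\\.exposure", rownames(sm$coefficients))
  est <- sm$coefficients[rows, "coef"]
  se <- sm$coefficients[rows, "se(coef)"]
  flag <- !all(is.finite(est)) || !all(is.finite(se)) || any(se > 50)
  lev <- sub("^\\.exposure", "", rownames(sm$coefficients)[rows])
  data.frame(
    exposure = ifelse(lev == "", name, paste0(name, ":", lev)),
    model = "cox", estimate = unname(est), se = unname(se),
    hr = exp(unname(est)),
    ci_low = exp(unname(est - 1.96 * se)),
    ci_high = exp(unname(est + 1.96 * se)),
    p = unname(sm$coefficients[rows, "Pr(>|z|)"]),
    n = nrow(df), n_events = n_events, flagged = flag,
    row.names = NULL, stringsAsFactors = FALSE)
}

flagged_result <- function(name, model, n, n_events = NA_integer_) {
  data.frame(exposure = name, model = model, estimate = NA_real_,
             se = NA_real_, hr = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p = NA_real_, n = n, n_events = n_events,
             flagged = TRUE, stringsAsFactors = FALSE)
}

#' Covariate-adjusted linear association with an age gap
#'
#' Ordinary least squares of the z-gap on one or more exposures plus
#' covariates. Serves the lifestyle, drug, progression and brain-volume
#' style analyses.
#'
#' @param gap Numeric response (z-scored age gap).
#' @param exposures Numeric vector, or data frame of simultaneous exposures.
#' @param covariates Data frame of covariates (may be `NULL`).
#' @return Data frame with one row per exposure: `exposure`, `model`,
#'   `estimate` (slope), `se`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
linear_association <- function(gap, exposures, covariates = NULL) {
  if (!is.data.frame(exposures))
    exposures <- data.frame(exposure = exposures)
  if (!is.null(covariates) && is.character(covariates$sex %||% NULL))
    covariates$sex <- sex_indicator(covariates$sex)
  X <- if (is.null(covariates)) exposures else cbind(exposures, covariates)
  stopifnot(nrow(X) == length(gap))
  mm <- stats::model.matrix(~ ., data = X)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(gap ~ ., data = X)
  sm <- summary(fit)
  exp_cols <- colnames(stats::model.matrix(~ ., data = exposures))[-1]
  exp_cols <- intersect(exp_cols, rownames(sm$coefficients))
  est <- sm$coefficients[exp_cols, "Estimate"]
  se <- sm$coefficients[exp_cols, "Std. Error"]
  data.frame(exposure = exp_cols, model = "linear",
             estimate = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             p = unname(sm$coefficients[exp_cols, "Pr(>|t|)"]),
             n = length(gap), row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate control; monotone in p and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Gini dispersion of per-organ log hazard ratios
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))` over the clipped log-HR vector.
#' Negative log HRs are clipped to 0 first (configurable): the statistic
#' measures how concentrated the disease's aging signal is across organs and
#' is ill-defined for mixed-sign inputs. G = 0 when all inputs are equal;
#' higher values mean a more organ-specific signal.
#'
#' @param log_hr Numeric vector (length >= 2) of per-organ log hazard ratios.
#' @param clip_negative Clip negative entries to zero first (default `TRUE`).
#' @return List `gini`, `clipped` (input after clipping), `flagged`
#'   (`TRUE` with `gini = NA` when the clipped vector is all zero).
#' @export
gini_of_log_hazards <- function(log_hr, clip_negative = TRUE) {
  stopifnot(is.numeric(log_hr), length(log_hr) >= 2)
  x <- if (clip_negative) pmax(log_hr, 0) else log_hr
  if (all(x == 0))
    return(list(gini = NA_real_, clipped = x, flagged = TRUE))
  n <- length(x)
  g <- sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  list(gini = g, clipped = x, flagged = FALSE)
}

#' Compare penalized Cox mortality models across feature sets
#'
#' For each named feature set, fits a lasso-regularized Cox model on the
#' training split (penalty chosen by cross-validated partial likelihood;
#' age and sex covariates always included and never penalized) and reports
#' Harrell's concordance index on the training and test splits.
#'
#' @param data Data frame with `time`, `status`, covariate and feature
#'   columns.
#' @param feature_sets Named list of character vectors of feature columns.
#' @param train_idx,test_idx Row indices of the train and test splits.
#' @param covariates Always-included covariate columns (default age, sex).
#' @param seed CV fold seed.
#' @return List with `concordance` (data frame: model, n_features,
#'   concordance_train, concordance_test) and `coefficients` (named list of
#'   fitted coefficient vectors, e.g. for the combined model).
#' @export
compare_mortality_models <- function(data, feature_sets, train_idx, test_idx,
                                     covariates = c("age", "sex"), seed = 1) {
  stopifnot(all(c("time", "status") %in% names(data)))
  if (is.character(data$sex %||% NULL)) data$sex <- sex_indicator(data$sex)
  if (any(vapply(feature_sets, length, integer(1)) == 0))
    stop("feature set(s) must be non-empty")
  res <- list(); coefs <- list()
  for (nm in names(feature_sets)) {
    cols <- c(covariates, feature_sets[[nm]])
    miss <- setdiff(cols, names(data))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    x <- as.matrix(data[, cols, drop = FALSE])
    y <- survival::Surv(data$time, data$status)
    pf <- c(rep(0, length(covariates)), rep(1, length(feature_sets[[nm]])))
    foldid <- with_seed(seed, sample(rep_len(1:5, length(train_idx))))
    cv <- glmnet::cv.glmnet(x[train_idx, , drop = FALSE], y[train_idx],
                            family = "cox", foldid = foldid,
                            penalty.factor = pf)
    lp_tr <- drop(stats::predict(cv, x[train_idx, , drop = FALSE], s = "lambda.min"))
    lp_te <- drop(stats::predict(cv, x[test_idx, , drop = FALSE], s = "lambda.min"))
    c_tr <- survival::concordance(y[train_idx] ~ lp_tr, reverse = TRUE)$concordance
    c_te <- survival::concordance(y[test_idx] ~ lp_te, reverse = TRUE)$concordance
    res[[nm]] <- data.frame(model = nm, n_features = length(feature_sets[[nm]]),
                            concordance_train = c_tr, concordance_test = c_te,
                            stringsAsFactors = FALSE)
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
    coefs[[nm]] <- cf
  }
  list(concordance = do.call(rbind, c(res, list(make.row.names = FALSE))),
       coefficients = coefs)
}

#' Kaplan-Meier product-limit curves per group
#'
#' Right-censored product-limit estimates, one step function per group, with
#' the cumulative incidence (1 - S) alongside for disease endpoints.
#'
#' @param records Data frame with `time` and `status`.
#' @param groups Group label per record (single group if omitted).
#' @return Data frame `group`, `time`, `survival`, `cum_incidence`,
#'   `at_risk`, `n_event`.
#' @export
km_curve <- function(records, groups = NULL) {
  stopifnot(all(c("time", "status") %in% names(records)))
  if (is.null(groups)) groups <- rep("all", nrow(records))
  if (any(table(groups) == 0)) stop("groups must be non-empty")
  df <- data.frame(time = records$time, status = records$status,
                   group = as.character(groups), stringsAsFactors = FALSE)
  out <- lapply(split(df, df$group), function(d) {
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    data.frame(group = d$group[1], time = sf$time, survival = sf$surv,
               cum_incidence = 1 - sf$surv, at_risk = sf$n.risk,
               n_event = sf$n.event, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
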