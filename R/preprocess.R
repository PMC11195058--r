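#' Split samples into train/test by collection centre
#'
#' Membership is determined solely by the centre a sample was collected at,
#' mirroring a centre-held-out evaluation design.
#'
#' @param samples Data frame with `sample_id` and `center` columns.
#' @param train_center_ids Character vector of training centres.
#' @return Object of class `sample_split`: list with `train_centers`,
#'   `test_centers`, `train_ids`, `test_ids` and a summary count table.
#' @export
split_by_center <- function(samples, train_center_ids) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "center") %in% names(samples)))
  bad <- samples$sample_id[is.na(samples$center) | samples$center == ""]
  if (length(bad))
    stop("sample(s) with unknown center: ", paste(utils::head(bad, 5), collapse = ", "))
  centers <- unique(samples$center)
  train_center_ids <- unique(as.character(train_center_ids))
  unknown <- setdiff(train_center_ids, centers)
  if (length(unknown))
    stop("train center(s) not present in samples: ", paste(unknown, collapse = ", "))
  if (length(train_center_ids) == 0) stop("train center set is empty")
  if (setequal(train_center_ids, centers))
    stop("train centers equal all centers; no test split remains")
  is_train <- samples$center %in% train_center_ids
  structure(list(
    train_centers = train_center_ids,
    test_centers = setdiff(centers, train_center_ids),
    train_ids = samples$sample_id[is_train],
    test_ids = samples$sample_id[!is_train],
    counts = c(n_train = sum(is_train), n_test = sum(!is_train))),
    class = "sample_split")
}

#' Filter proteins with high missingness
#'
#' A protein is removed only when its missing fraction is strictly over the
#' threshold ("over 10%" read literally).
#'
#' @param matrix Samples x proteins numeric matrix with `NA` for missing.
#' @param threshold Missing-fraction threshold in (0, 1); default 0.10.
#' @return List with `retained` (protein names), `removed` (data frame
#'   protein, missing_fraction) and `threshold`.
#' @export
filter_high_missingness <- function(matrix, threshold = 0.10) {
  stopifnot(is.matrix(matrix), threshold > 0, threshold < 1)
  frac <- colMeans(is.na(matrix))
  drop <- frac > threshold
  list(retained = colnames(matrix)[!drop],
       removed = data.frame(protein = colnames(matrix)[drop],
                            missing_fraction = unname(frac[drop]),
                            stringsAsFactors = FALSE),
       threshold = threshold)
}

#' Neighbour count for KNN imputation
#'
#' k is the square root of the training sample size, rounded to the nearest
#' integer (minimum 1): 21,504 training samples give k = 147.
#'
#' @param n_train Training sample count (>= 1).
#' @return Integer k.
#' @export
choose_k <- function(n_train) {
  stopifnot(n_train >= 1)
  max(1L, as.integer(round(sqrt(n_train))))
}

#' Fit a KNN imputation model on training samples
#'
#' @param train Samples x proteins training matrix (may contain `NA`).
#' @param k Neighbour count; defaults to [choose_k()] of the training size.
#' @return Object of class `imputation_model` holding the training reference,
#'   `k` and the protein list.
#' @export
fit_impute <- function(train, k = NULL) {
  stopifnot(is.matrix(train), !is.null(colnames(train)))
  k <- k %||% choose_k(nrow(train))
  stopifnot(k >= 1)
  structure(list(train = train, k = as.integer(k),
                 proteins = colnames(train),
                 col_means = colMeans(train, na.rm = TRUE)),
            class = "imputation_model")
}

# Squared nan-Euclidean distances between rows of X and rows of T:
# mean squared difference over co-observed coordinates, rescaled by the total
# feature count (standard KNN-imputer semantics). Inf when nothing co-observed.
nan_euclidean_sq <- function(X, B) {
  p <- ncol(X)
  Mx <- !is.na(X); Mt <- !is.na(B)
  X0 <- X; X0[!Mx] <- 0
  T0 <- B; T0[!Mt] <- 0
  cross <- X0 %*% t(T0)
  ssx <- (X0^2) %*% t(Mt)
  sst <- Mx %*% t(T0^2)
  n_co <- Mx %*% t(Mt)
  d2 <- (ssx + sst - 2 * cross) * p / pmax(n_co, 1)
  d2[n_co == 0] <- Inf
  pmax(d2, 0)
}

#' Impute missing values with a fitted KNN model
#'
#' Each missing entry is replaced by the mean of that protein's values in the
#' `k` nearest training samples (nan-Euclidean distance over co-observed
#' proteins), considering only training samples with the protein observed.
#' Observed entries are never altered. If no eligible donor exists the
#' training column mean is used.
#'
#' @param model An `imputation_model` from [fit_impute()].
#' @param matrix Samples x proteins matrix; proteins must be a subset of the
#'   model's protein list.
#' @return The matrix with no missing values.
#' @export
apply_impute <- function(model, matrix) {
  stopifnot(inherits(model, "imputation_model"), is.matrix(matrix))
  if (!all(colnames(matrix) %in% model$proteins))
    stop("matrix contains proteins absent from the imputation model")
  all_missing <- rowSums(!is.na(matrix)) == 0
  if (any(all_missing))
    stop("sample(s) with all proteins missing: ",
         paste(utils::head(rownames(matrix)[all_missing], 5), collapse = ", "))
  if (!anyNA(matrix)) return(matrix)

  Tr <- model$train[, colnames(matrix), drop = FALSE]
  d2 <- nan_euclidean_sq(matrix, Tr)
  out <- matrix
  for (i in which(rowSums(is.na(matrix)) > 0)) {
    ord <- order(d2[i, ])
    ord <- ord[is.finite(d2[i, ord])]
    for (j in which(is.na(matrix[i, ]))) {
      donors <- ord[!is.na(Tr[ord, j])]
      if (length(donors) == 0) {
        out[i, j] <- model$col_means[colnames(matrix)[j]]
      } else {
        donors <- donors[seq_len(min(model$k, length(donors)))]
        out[i, j] <- mean(Tr[donors, j])
      }
    }
  }
  out
}

#' Fit a train-anchored z-score scaler
#'
#' @param train Complete training matrix (samples x proteins).
#' @return Object of class `scaler_params` with per-protein training means
#'   and SDs.
#' @export
fit_scaler <- function(train) {
  stopifnot(is.matrix(train), !anyNA(train))
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  zero <- sd <= 0 | !is.finite(sd)
  if (any(zero))
    stop("zero-variance training protein(s): ",
         paste(colnames(train)[zero], collapse = ", "))
  structure(list(mean = mu, sd = sd, proteins = colnames(train)),
            class = "scaler_params")
}

#' Apply training z-score parameters to a matrix
#'
#' Test columns are transformed with the training means and SDs, never their
#' own.
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param matrix Samples x proteins matrix.
#' @return Standardized matrix.
#' @export
apply_scaler <- function(params, matrix) {
  stopifnot(inherits(params, "scaler_params"), is.matrix(matrix))
  if (!all(colnames(matrix) %in% params$proteins))
    stop("matrix contains proteins absent from the scaler")
  mu <- params$mean[colnames(matrix)]
  sd <- params$sd[colnames(matrix)]
  sweep(sweep(matrix, 2, mu, "-"), 2, sd, "/")
}

#' Run the full preprocessing contract
#'
#' Enforces the fixed order: missingness filter (computed on the combined
#' matrix) -> KNN imputation fitted on training samples (k = sqrt(n_train))
#' -> train-anchored z-scoring. Returns analysis-ready train and test
#' matrices plus a manifest of parameters.
#'
#' @param matrix Combined samples x proteins matrix (`NA` = missing).
#' @param split A `sample_split` from [split_by_center()].
#' @param threshold Missingness threshold for [filter_high_missingness()].
#' @param k Optional neighbour count override.
#' @return List with `train`, `test` (standardized complete matrices),
#'   `imputer`, `scaler`, `filter`, and `manifest` (ordered stage record).
#' @export
preprocess <- function(matrix, split, threshold = 0.10, k = NULL) {
  stopifnot(inherits(split, "sample_split"))
  flt <- filter_high_missingness(matrix, threshold)
  m <- matrix[, flt$retained, drop = FALSE]
  tr <- m[rownames(m) %in% split$train_ids, , drop = FALSE]
  te <- m[rownames(m) %in% split$test_ids, , drop = FALSE]
  imp <- fit_impute(tr, k = k)
  tr_i <- apply_impute(imp, tr)
  te_i <- if (nrow(te)) apply_impute(imp, te) else te
  sc <- fit_scaler(tr_i)
  list(train = apply_scaler(sc, tr_i),
       test = if (nrow(te)) apply_scaler(sc, te_i) else te_i,
       imputer = imp, scaler = sc, filter = flt,
       manifest = list(
         order = c("filter_high_missingness", "knn_impute", "z_scale"),
         threshold = threshold, k = imp$k,
         n_train = nrow(tr), n_test = nrow(te),
         n_proteins_removed = nrow(flt$removed)))
}
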