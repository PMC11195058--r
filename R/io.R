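#' Write a samples x proteins matrix as TSV
#'
#' First column `sample_id`; missing entries are written as empty cells.
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a samples x proteins TSV matrix
#' @param path Path written by [write_matrix_tsv()] (empty cell = missing).
#' @return Numeric matrix with sample-id row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Serialize a cohort bundle to a directory
#'
#' Proteomics matrices as TSV (one per visit), subjects/visits/events as
#' CSV, latent gaps as CSV, and the full generator ground truth (config,
#' loadings, event linear predictors) as JSON.
#'
#' @param cohort A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$gaps, file.path(dir, "gaps.csv"), row.names = FALSE)
  for (v in seq_along(cohort$proteome))
    write_matrix_tsv(cohort$proteome[[v]],
                     file.path(dir, sprintf("proteome_visit%d.tsv", v)))
  for (e in names(cohort$events))
    utils::write.csv(cohort$events[[e]],
                     file.path(dir, sprintf("events_%s.csv", e)), row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  truth$config$hazard_specs <- lapply(truth$config$hazard_specs, function(h) {
    h <- unclass(h); h$log_hr <- as.list(h$log_hr); h
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a serialized cohort bundle
#' @param dir Directory written by [write_cohort()].
#' @return A `cohort_bundle` (gap matrices are rebuilt from the long table).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE)
  gaps <- utils::read.csv(file.path(dir, "gaps.csv"), stringsAsFactors = FALSE)
  prot_files <- sort(list.files(dir, pattern = "^proteome_visit\\d+\\.tsv$",
                                full.names = TRUE))
  proteome <- lapply(prot_files, read_matrix_tsv)
  ev_files <- list.files(dir, pattern = "^events_.*\\.csv$", full.names = TRUE)
  events <- lapply(ev_files, utils::read.csv, stringsAsFactors = FALSE)
  names(events) <- sub("^events_(.*)\\.csv$", "\\1", basename(ev_files))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  factors <- unique(gaps$organ)
  gap_mats <- lapply(sort(unique(gaps$visit)), function(v) {
    g <- gaps[gaps$visit == v, ]
    m <- matrix(NA_real_, nrow(subjects), length(factors),
                dimnames = list(subjects$subject_id, factors))
    m[cbind(match(g$subject_id, subjects$subject_id),
            match(g$organ, factors))] <- g$true_gap
    m
  })
  structure(list(subjects = subjects, visits = visits, gaps = gaps,
                 gap_matrices = gap_mats, proteome = proteome,
                 events = events, truth = truth),
            class = "cohort_bundle")
}

#' Serialize a clock model to JSON
#' @param clock A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_json <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  x <- unclass(clock)
  x$weights <- as.list(x$weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a clock model from JSON
#' @param path Path written by [write_clock_json()].
#' @return A `clock_model`.
#' @export
read_clock_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(x$weights)
  if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
  cl <- clock_model(x$name, weights = w, intercept = x$intercept,
                    residualizer = x$residualizer, gap_mean = x$gap_mean,
                    gap_sd = x$gap_sd, panel = x$panel,
                    predictive = x$predictive)
  cl$lambda <- x$lambda %||% NA_real_
  cl$cv_record <- x$cv_record
  cl$train_r <- x$train_r
  cl
}
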