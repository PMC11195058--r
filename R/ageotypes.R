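#' Bin a z-scored age gap into 0.5-SD bins
#'
#' Eight ordinal bins with edges at -1.5, -1.0, -0.5, 0, 0.5, 1.0, 1.5;
#' interior bins are left-closed right-open, the outer bins unbounded
#' (z >= 1.5 is the top bin, z < -1.5 the bottom).
#'
#' @param z Finite numeric vector of z-gaps.
#' @return Ordered factor over the 8 bin labels.
#' @export
bin_gap <- function(z) {
  if (any(!is.finite(z))) stop("z-gaps must be finite")
  edges <- seq(-1.5, 1.5, by = 0.5)
  labels <- c("(-Inf,-1.5)", "[-1.5,-1)", "[-1,-0.5)", "[-0.5,0)",
              "[0,0.5)", "[0.5,1)", "[1,1.5)", "[1.5,Inf)")
  idx <- findInterval(z, edges) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Classify samples into extreme-ager ageotypes
#'
#' A model's gap is extreme when `|z| >= threshold` (1.5 SD). A sample with
#' no extreme gap is a normal ager; exactly one extreme gap makes a
#' single-organ ager (aged or youthful by the gap's sign); two or more
#' extreme gaps of the same sign make a multi-organ ager (binned 2-4, 5-7,
#' 8+); extreme gaps of both signs are ambiguous. The conventional clock is
#' excluded from eligibility.
#'
#' @param z Samples x models matrix of z-gaps.
#' @param threshold Extreme-ager threshold (default 1.5).
#' @param exclude Models excluded from eligibility (default
#'   `"conventional"`).
#' @param multi_bins Lower edges of the multi-organ count bins (default
#'   `c(2, 5, 8)` giving 2-4 / 5-7 / 8+).
#' @return Data frame `sample_id`, `category` (normal / single_organ /
#'   multi_organ / ambiguous), `direction` (aged / youthful / mixed / none),
#'   `organs` (semicolon-separated), `n_extreme`, `bin` (multi-organ count
#'   bin or `NA`).
#' @export
classify_ageotypes <- function(z, threshold = 1.5, exclude = "conventional",
                               multi_bins = c(2, 5, 8)) {
  stopifnot(is.matrix(z), !is.null(colnames(z)))
  eligible <- setdiff(colnames(z), exclude)
  if (length(eligible) == 0) stop("no eligible models after exclusion")
  zm <- z[, eligible, drop = FALSE]
  if (anyNA(zm)) {
    bad <- colnames(zm)[colSums(is.na(zm)) > 0]
    stop("missing z-gap for eligible model(s): ", paste(bad, collapse = ", "))
  }
  bin_labels <- c(paste0(multi_bins[1], "-", multi_bins[2] - 1),
                  paste0(multi_bins[2], "-", multi_bins[3] - 1),
                  paste0(multi_bins[3], "+"))
  out <- lapply(seq_len(nrow(zm)), function(i) {
    zi <- zm[i, ]
    ext <- which(abs(zi) >= threshold)
    n <- length(ext)
    if (n == 0) {
      list(category = "normal", direction = "none", organs = "", bin = NA_character_)
    } else {
      signs <- sign(zi[ext])
      organs <- paste(eligible[ext], collapse = ";")
      if (any(signs > 0) && any(signs < 0)) {
        list(category = "ambiguous", direction = "mixed", organs = organs,
             bin = NA_character_)
      } else if (n == 1) {
        list(category = "single_organ",
             direction = if (signs[1] > 0) "aged" else "youthful",
             organs = organs, bin = NA_character_)
      } else {
        bi <- findInterval(n, multi_bins)
        list(category = "multi_organ",
             direction = if (signs[1] > 0) "aged" else "youthful",
             organs = organs, bin = bin_labels[bi])
      }
    }
  })
  data.frame(
    sample_id = rownames(zm) %||% seq_len(nrow(zm)),
    category = vapply(out, `[[`, character(1), "category"),
    direction = vapply(out, `[[`, character(1), "direction"),
    organs = vapply(out, `[[`, character(1), "organs"),
    n_extreme = vapply(seq_len(nrow(zm)),
                       function(i) sum(abs(zm[i, ]) >= threshold), numeric(1)),
    bin = vapply(out, `[[`, character(1), "bin"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-visit extreme-ager transition statistics for one organ
#'
#' For paired z-gaps at two visits: the repeat risk ratio
#' `P(extreme at v2 | extreme at v1) / P(extreme at v2 | not extreme at v1)`
#' and, among visit-1 extreme agers, the fraction whose visit-2 z-gap keeps
#' the same sign (plus identical-0.5-SD-bin retention as a secondary
#' statistic). Counts are reported alongside the ratios.
#'
#' @param z1,z2 Paired z-gap vectors (same subjects, visits 1 and 2).
#' @param threshold Extreme threshold (1.5).
#' @param direction `"any"` (|z| >= threshold), `"aged"` (z >= threshold) or
#'   `"youthful"` (z <= -threshold).
#' @return List with `repeat_risk_ratio` (`NA` + `flagged = TRUE` when the
#'   denominator is degenerate), `same_sign_retention`,
#'   `same_bin_retention`, and a `counts` vector.
#' @export
transition_stats <- function(z1, z2, threshold = 1.5,
                             direction = c("any", "aged", "youthful")) {
  direction <- match.arg(direction)
  stopifnot(length(z1) == length(z2))
  is_ext <- switch(direction,
                   any = function(z) abs(z) >= threshold,
                   aged = function(z) z >= threshold,
                   youthful = function(z) z <= -threshold)
  e1 <- is_ext(z1); e2 <- is_ext(z2)
  n11 <- sum(e1 & e2); n10 <- sum(e1 & !e2)
  n01 <- sum(!e1 & e2); n00 <- sum(!e1 & !e2)
  flagged <- sum(e1) == 0 || sum(!e1) == 0 || n01 == 0
  rrr <- if (flagged) NA_real_ else (n11 / sum(e1)) / (n01 / sum(!e1))
  same_sign <- if (sum(e1) == 0) NA_real_ else
    mean(sign(z2[e1]) == sign(z1[e1]))
  same_bin <- if (sum(e1) == 0) NA_real_ else
    mean(bin_gap(z2[e1]) == bin_gap(z1[e1]))
  list(repeat_risk_ratio = rrr, flagged = flagged,
       same_sign_retention = same_sign, same_bin_retention = same_bin,
       counts = c(n_ext1 = sum(e1), n_nonext1 = sum(!e1),
                  n11 = n11, n10 = n10, n01 = n01, n00 = n00))
}
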