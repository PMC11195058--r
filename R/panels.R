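#' Read a tissue expression atlas from TSV
#'
#' First column gene identifier, remaining columns organs; values are
#' non-negative TPM-like expression.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix genes x organs with gene row names.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_atlas(m)
  m
}

validate_atlas <- function(atlas) {
  if (!is.matrix(atlas) || !is.numeric(atlas)) stop("atlas must be a numeric matrix")
  if (is.null(rownames(atlas)) || anyDuplicated(rownames(atlas)))
    stop("atlas gene identifiers must be present and unique")
  if (is.null(colnames(atlas)) || anyDuplicated(colnames(atlas)))
    stop("atlas organ names must be present and unique")
  if (any(atlas < 0, na.rm = TRUE)) stop("atlas expression values must be non-negative")
  invisible(atlas)
}

#' Call organ-enriched genes from an expression atlas
#'
#' A gene is assigned to an organ when its expression there is at least
#' `fold` times its expression in any other organ (inclusive threshold). A
#' gene expressed in exactly one organ and zero elsewhere is enriched there
#' (the ratio is treated as infinite); an all-zero gene is unassigned. For
#' `fold > 1` at most one organ can satisfy the rule.
#'
#' @param atlas Numeric matrix genes x organs (see [read_atlas()]).
#' @param fold Fold-change threshold, > 1 (default 4).
#' @return Data frame with one row per gene: `gene`, `organ` (`NA` when
#'   unassigned), `max_expr`, `second_expr`, `fold_ratio`.
#' @export
select_organ_enriched_genes <- function(atlas, fold = 4) {
  validate_atlas(atlas)
  if (ncol(atlas) < 2)
    stop("enrichment is undefined for an atlas with a single organ")
  if (fold <= 1) stop("fold threshold must be > 1")
  top_idx <- max.col(atlas, ties.method = "first")
  top <- atlas[cbind(seq_len(nrow(atlas)), top_idx)]
  rest <- atlas
  rest[cbind(seq_len(nrow(atlas)), top_idx)] <- -Inf
  second <- apply(rest, 1, max)
  ratio <- ifelse(second > 0, top / second, ifelse(top > 0, Inf, NA_real_))
  enriched <- top > 0 & (second == 0 | top >= fold * second)
  # exact tie at the top (top == second > 0) can never satisfy fold > 1
  data.frame(gene = rownames(atlas),
             organ = ifelse(enriched, colnames(atlas)[top_idx], NA_character_),
             max_expr = top, second_expr = second, fold_ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build organ-specific, organismal and conventional protein panels
#'
#' Maps organ-enriched genes onto the assay's protein list. A protein joins
#' an organ panel if any gene mapping to it is enriched in that organ; with
#' several enriched genes the organ of the highest-fold gene is kept. The
#' organismal panel is every assay protein in no organ panel; the
#' conventional panel is the full assay.
#'
#' @param gene_map Output of [select_organ_enriched_genes()].
#' @param assay_proteins Character vector of proteins measured on the assay.
#' @param mapping Two-column data frame (`gene`, `protein`); defaults to the
#'   identity mapping (protein ids are gene ids).
#' @param atlas_id Optional provenance string naming the atlas.
#' @param fold Fold threshold recorded as provenance.
#' @return Object of class `organ_panels`: list with `panels` (named list of
#'   protein vectors including `organismal` and `conventional`), `provenance`
#'   and `empty_organs` (organs whose panels were omitted, with a warning).
#' @export
build_panels <- function(gene_map, assay_proteins, mapping = NULL,
                         atlas_id = "atlas", fold = 4) {
  stopifnot(is.data.frame(gene_map), all(c("gene", "organ") %in% names(gene_map)))
  assay_proteins <- unique(as.character(assay_proteins))
  if (is.null(mapping))
    mapping <- data.frame(gene = assay_proteins, protein = assay_proteins,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "protein") %in% names(mapping)))

  enr <- gene_map[!is.na(gene_map$organ), , drop = FALSE]
  hit <- merge(mapping, enr, by = "gene")
  hit <- hit[hit$protein %in% assay_proteins, , drop = FALSE]
  prot_organ <- character(0)
  if (nrow(hit)) {
    # many-to-one: keep the organ of the highest-fold enriched gene
    hit <- hit[order(hit$protein, -hit$fold_ratio), , drop = FALSE]
    hit <- hit[!duplicated(hit$protein), , drop = FALSE]
    prot_organ <- stats::setNames(hit$organ, hit$protein)
  }

  organs_seen <- sort(unique(gene_map$organ[!is.na(gene_map$organ)]))
  panels <- lapply(organs_seen, function(o) names(prot_organ)[prot_organ == o])
  names(panels) <- organs_seen
  empty <- names(panels)[vapply(panels, length, integer(1)) == 0]
  if (length(empty)) {
    warning("no assay protein maps to enriched genes of: ",
            paste(empty, collapse = ", "), "; panel(s) omitted")
    panels <- panels[setdiff(names(panels), empty)]
  }
  organ_prots <- unlist(panels, use.names = FALSE)
  panels$organismal <- setdiff(assay_proteins, organ_prots)
  panels$conventional <- assay_proteins
  structure(list(
    panels = panels,
    provenance = list(fold = fold, atlas = atlas_id,
                      n_assay = length(assay_proteins)),
    empty_organs = empty), class = "organ_panels")
}

#' Assign each gene to the group with maximal expression
#'
#' Used e.g. to attribute clock proteins to the cell type with the highest
#' expression of the encoding gene. Exact ties and all-zero genes are
#' unassigned (ties flagged).
#'
#' @param expression Numeric matrix genes x groups (>= 2 groups).
#' @return Data frame `gene`, `group` (`NA` when unassigned), `tie` (logical).
#' @export
assign_max_expression_label <- function(expression) {
  stopifnot(is.matrix(expression), ncol(expression) >= 2)
  top_idx <- max.col(expression, ties.method = "first")
  top <- expression[cbind(seq_len(nrow(expression)), top_idx)]
  n_at_top <- rowSums(expression == top)
  tie <- n_at_top > 1
  group <- ifelse(top > 0 & !tie, colnames(expression)[top_idx], NA_character_)
  data.frame(gene = rownames(expression) %||% seq_len(nrow(expression)),
             group = group, tie = tie & top > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write panels to JSON
#' @param panels An `organ_panels` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panels_json <- function(panels, path) {
  stopifnot(inherits(panels, "organ_panels"))
  jsonlite::write_json(list(panels = panels$panels,
                            provenance = panels$provenance,
                            empty_organs = panels$empty_organs),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read panels from JSON
#' @param path Path written by [write_panels_json()].
#' @return An `organ_panels` object.
#' @export
read_panels_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(panels = as.list(x$panels), provenance = x$provenance,
                 empty_organs = x$empty_organs %||% character(0)),
            class = "organ_panels")
}

#' Synthetic expression atlas consistent with a cohort's planted panels
#'
#' Builds an organ x gene atlas in which each planted organ-panel gene is
#' expressed well above the four-fold enrichment threshold in its organ, and
#' organismal genes are expressed evenly (never enriched). Used to exercise
#' the enrichment caller against generator ground truth.
#'
#' @param cohort A `cohort_bundle`.
#' @param high Expression in the enriched organ.
#' @param low Expression elsewhere.
#' @return Numeric matrix genes x organs.
#' @export
truth_atlas <- function(cohort, high = 50, low = 2) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  ld <- cohort$truth$loadings
  organs <- cohort$truth$config$organs
  m <- matrix(low, nrow(ld), length(organs),
              dimnames = list(ld$protein, organs))
  org_rows <- ld$organ != "organismal"
  m[cbind(which(org_rows), match(ld$organ[org_rows], organs))] <- high
  m
}
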