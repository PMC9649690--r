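#' Construct an expression atlas
#'
#' An `ExpressionAtlas` bundles a transcript-by-cell-line TPM matrix with the
#' mapping from cell lines to lineages. It is the substrate for lineage
#' aggregation, specificity scoring, and drug association.
#'
#' @param values numeric matrix of TPM, rows = transcripts, columns = cell
#'   lines; must be non-negative with unique, non-missing dimnames.
#' @param lineage_of named character vector mapping every cell line (names)
#'   to its lineage label.
#' @return An object of class `ExpressionAtlas`: a list with elements
#'   `values` (the matrix) and `lineage_of` (the map, reordered to the
#'   column order of `values`).
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("c1", "c2")))
#' atlas <- expression_atlas(m, c(c1 = "lung", c2 = "skin"))
#' @export
expression_atlas <- function(values, lineage_of) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have transcript rownames and cell-line colnames",
         call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-line ids in expression matrix", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("TPM values must be non-negative and non-missing", call. = FALSE)
  missing_lab <- setdiff(colnames(values), names(lineage_of))
  if (length(missing_lab))
    stop("cell lines without a lineage label: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  lin <- stats::setNames(as.character(lineage_of[colnames(values)]),
                         colnames(values))
  structure(list(values = values, lineage_of = lin), class = "ExpressionAtlas")
}

#' @exportS3Method base::print
print.ExpressionAtlas <- function(x, ...) {
  cat("ExpressionAtlas:", nrow(x$values), "transcripts x",
      ncol(x$values), "cell lines,",
      length(unique(x$lineage_of)), "lineages\n")
  invisible(x)
}

#' @export
dim.ExpressionAtlas <- function(x) dim(x$values)

#' Load an expression atlas from disk
#'
#' Reads a transcript-by-cell-line TPM table (TSV with the transcript id in
#' the first column, or MatrixMarket triplet plus id sidecars) together with
#' a two-column cell-line-to-lineage TSV, and validates the atlas invariants.
#'
#' @param path expression file: TSV (first column transcript id, remaining
#'   columns one per cell line) or `.mtx` MatrixMarket file. For MTX,
#'   `<path>.rownames` and `<path>.colnames` sidecar files supply the ids,
#'   one per line.
#' @param lineage_path two-column TSV (cell_line, lineage) with header.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @return An [expression_atlas()] object.
#' @seealso [write_expression()] for the inverse operation.
#' @export
load_expression <- function(path, lineage_path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("expression TSV needs an id column plus >=1 cell line",
                            call. = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path, call. = FALSE)
    rownames(m) <- ids
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".rownames"))
    colnames(m) <- readLines(paste0(path, ".colnames"))
  }
  lin <- utils::read.delim(lineage_path, stringsAsFactors = FALSE)
  lineage_of <- stats::setNames(as.character(lin[[2]]), as.character(lin[[1]]))
  expression_atlas(m, lineage_of)
}

#' Write an expression atlas to disk
#'
#' @param atlas an [expression_atlas()] object.
#' @param path output expression file (TSV or `.mtx`).
#' @param lineage_path output lineage-map TSV; omit to skip.
#' @param format `"tsv"` or `"mtx"` (MTX writes `.rownames`/`.colnames`
#'   sidecars).
#' @return `path`, invisibly.
#' @export
write_expression <- function(atlas, path, lineage_path = NULL,
                             format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- data.frame(transcript_id = rownames(atlas$values),
                      atlas$values, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(atlas$values, sparse = TRUE), path)
    writeLines(rownames(atlas$values), paste0(path, ".rownames"))
    writeLines(colnames(atlas$values), paste0(path, ".colnames"))
  }
  if (!is.null(lineage_path)) {
    utils::write.table(
      data.frame(cell_line = names(atlas$lineage_of),
                 lineage = unname(atlas$lineage_of)),
      lineage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter transcripts by expression prevalence
#'
#' Retains transcripts that reach a TPM threshold in a minimum number (or
#' fraction) of cell lines. Two comparison dialects are in common use and
#' both are supported: the atlas-building filter keeps transcripts with
#' expression at or above the threshold in at least one cell line
#' (inclusive, `mode = "inclusive"`), while the drug-association filter
#' removes transcripts expressed strictly above the threshold in less than a
#' fifth of cell lines (strict, `mode = "strict"`).
#'
#' @param atlas an [expression_atlas()] object.
#' @param min_tpm TPM threshold (default 0.1).
#' @param min_fraction minimum fraction of cell lines that must pass;
#'   mutually exclusive with `min_count`.
#' @param min_count minimum number of cell lines that must pass (default 1).
#' @param mode `"inclusive"` compares `>= min_tpm`, `"strict"` compares
#'   `> min_tpm`.
#' @return A new `ExpressionAtlas` restricted to passing transcripts; the
#'   input is not modified.
#' @export
prevalence_filter <- function(atlas, min_tpm = 0.1, min_fraction = NULL,
                              min_count = 1, mode = c("inclusive", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(atlas, "ExpressionAtlas"), min_tpm >= 0)
  pass <- if (mode == "inclusive") atlas$values >= min_tpm else atlas$values > min_tpm
  n_pass <- rowSums(pass)
  need <- if (!is.null(min_fraction)) {
    stopifnot(min_fraction >= 0, min_fraction <= 1)
    min_fraction * ncol(atlas$values)
  } else {
    min_count
  }
  keep <- n_pass >= need
  expression_atlas(atlas$values[keep, , drop = FALSE], atlas$lineage_of)
}

#' Aggregate an atlas by lineage
#'
#' Collapses cell-line columns to one column per lineage (by default the
#' mean TPM over the lineage's cell lines) and derives per-transcript
#' expression ratios: the aggregated expression of transcript *t* in lineage
#' *i* divided by its sum over all lineages. Transcripts with zero total
#' expression have undefined ratios and are flagged rather than scored.
#'
#' @param atlas an [expression_atlas()] object.
#' @param method aggregation over a lineage's cell lines: `"mean"`
#'   (default), `"median"`, or `"sum"`.
#' @return A `LineageProfile`: list with `x` (transcript x lineage aggregated
#'   TPM), `p` (expression-ratio matrix, rows summing to 1; `NA` rows for
#'   zero-expression transcripts), `N` (lineage count), and `undefined`
#'   (logical flag per transcript).
#' @export
aggregate_by_lineage <- function(atlas, method = c("mean", "median", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(atlas, "ExpressionAtlas"))
  lineages <- sort(unique(atlas$lineage_of))
  if (any(table(atlas$lineage_of) < 1L)) stop("empty lineage", call. = FALSE)
  agg <- switch(method,
    mean = function(m) rowMeans(m),
    median = function(m) apply(m, 1, stats::median),
    sum = function(m) rowSums(m))
  x <- vapply(lineages, function(l) {
    cols <- names(atlas$lineage_of)[atlas$lineage_of == l]
    agg(atlas$values[, cols, drop = FALSE])
  }, numeric(nrow(atlas$values)))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(rownames(atlas$values), lineages))
  tot <- rowSums(x)
  undefined <- tot <= 0
  p <- x / tot
  p[undefined, ] <- NA_real_
  structure(list(x = x, p = p, N = length(lineages), undefined = undefined),
            class = "LineageProfile")
}

#' Lineage-specificity scores from a lineage profile
#'
#' The specificity score of a transcript is the log2 of the lineage count
#' minus the Shannon entropy of its expression-ratio distribution across
#' lineages:
#' \deqn{S_t = \log_2(N) + \sum_{i=1}^{N} p_{it} \log_2 p_{it}}
#' with the convention \eqn{0 \cdot \log_2 0 = 0}. A uniformly expressed
#' transcript scores 0; a transcript confined to a single lineage scores
#' \eqn{\log_2 N}. Transcripts with undefined ratios (zero total expression)
#' are skipped and carry `NA` scores.
#'
#' @param profile a `LineageProfile` from [aggregate_by_lineage()].
#' @return A data.frame with one row per transcript: `transcript_id`,
#'   `score`, `top_lineage`, `top_ratio`, `second_ratio`, `undefined`.
#' @export
specificity_scores <- function(profile) {
  stopifnot(inherits(profile, "LineageProfile"))
  p <- profile$p
  plogp <- p * log2(p)
  plogp[p == 0] <- 0            # 0 * log2(0) := 0
  entropy <- -rowSums(plogp)
  score <- log2(profile$N) - entropy
  lineages <- colnames(p)
  top_idx <- apply(p, 1, function(r) if (anyNA(r)) NA_integer_ else which.max(r))
  top_ratio <- vapply(seq_len(nrow(p)), function(i)
    if (is.na(top_idx[i])) NA_real_ else p[i, top_idx[i]], numeric(1))
  second_ratio <- vapply(seq_len(nrow(p)), function(i) {
    if (is.na(top_idx[i])) return(NA_real_)
    r <- p[i, -top_idx[i]]
    if (length(r)) max(r) else 0
  }, numeric(1))
  data.frame(
    transcript_id = rownames(p),
    score = ifelse(profile$undefined, NA_real_, score),
    top_lineage = ifelse(is.na(top_idx), NA_character_, lineages[top_idx]),
    top_ratio = top_ratio,
    second_ratio = second_ratio,
    undefined = profile$undefined,
    row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Call lineage-specific transcripts
#'
#' A transcript is called lineage-specific in its top lineage when its
#' largest expression ratio is more than twice the second largest and its
#' specificity score exceeds 1 (both comparisons strict). For analyses that
#' apply only the score threshold (as done for RBP gene specificity), the
#' ratio condition can be disabled.
#'
#' @param scores data.frame from [specificity_scores()].
#' @param score_min score threshold, exceeded strictly (default 1).
#' @param ratio_rule apply the 2x top-vs-second ratio condition (default
#'   `TRUE`).
#' @return The input with columns `is_specific` (logical) and
#'   `called_lineage` (top lineage for calls, `NA` otherwise) appended.
#' @export
call_lineage_specific <- function(scores, score_min = 1, ratio_rule = TRUE) {
  ratio_ok <- if (ratio_rule) {
    !is.na(scores$top_ratio) & scores$top_ratio > 2 * scores$second_ratio
  } else {
    rep(TRUE, nrow(scores))
  }
  is_specific <- !is.na(scores$score) & scores$score > score_min & ratio_ok
  scores$is_specific <- is_specific
  scores$called_lineage <- ifelse(is_specific, scores$top_lineage, NA_character_)
  scores
}
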