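#' Filter a knockdown differential-expression table for significance
#'
#' Retains transcripts significantly changed upon RBP knockdown:
#' absolute linear fold change strictly above `fc_threshold` and FDR
#' strictly below `fdr_threshold`.
#'
#' @param de data.frame with columns `transcript_id`, `log2fc`, `fdr` (an
#'   `rbp_id` column is carried through if present).
#' @param fc_threshold linear fold-change threshold (default 1.5, i.e.
#'   `|log2fc| > log2(1.5)`).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return The significant subset of `de`.
#' @export
filter_significant <- function(de, fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(all(c("transcript_id", "log2fc", "fdr") %in% names(de)),
            fc_threshold >= 1, fdr_threshold > 0)
  keep <- abs(de$log2fc) > log2(fc_threshold) & de$fdr < fdr_threshold
  de[keep, , drop = FALSE]
}

peaks_to_granges <- function(peaks) {
  if (methods::is(peaks, "GRanges")) return(peaks)
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start, end = peaks$end),
    strand = if ("strand" %in% names(peaks)) peaks$strand else "*")
}

exon_granges <- function(models) {
  rows <- lapply(models, function(m)
    data.frame(chrom = m$chrom, start = m$exons[, 1], end = m$exons[, 2],
               strand = m$strand, transcript_id = m$id,
               stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  GenomicRanges::GRanges(tab$chrom,
                         IRanges::IRanges(tab$start, tab$end),
                         strand = tab$strand,
                         transcript_id = tab$transcript_id)
}

span_granges <- function(models) {
  GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(models, function(m) model_span(m)[1], numeric(1)),
                     vapply(models, function(m) model_span(m)[2], numeric(1))),
    strand = vapply(models, `[[`, character(1), "strand"),
    transcript_id = vapply(models, `[[`, character(1), "id"))
}

count_peak_hits <- function(peaks_gr, target_gr) {
  # same-strand when the peak carries a strand, strand-agnostic otherwise
  stranded <- as.character(BiocGenerics::strand(peaks_gr)) %in% c("+", "-")
  hits_per_tx <- function(gr, ignore_strand) {
    ov <- GenomicRanges::findOverlaps(gr, target_gr,
                                      ignore.strand = ignore_strand)
    tx <- target_gr$transcript_id[S4Vectors::subjectHits(ov)]
    # one peak may hit several exons of one transcript: count distinct peaks
    tapply(S4Vectors::queryHits(ov), tx,
           function(q) length(unique(q)), default = 0L)
  }
  counts <- list()
  if (any(stranded)) counts <- c(counts, list(hits_per_tx(peaks_gr[stranded], FALSE)))
  if (any(!stranded)) counts <- c(counts, list(hits_per_tx(peaks_gr[!stranded], TRUE)))
  all_tx <- unique(unlist(lapply(counts, names)))
  total <- stats::setNames(rep(0L, length(all_tx)), all_tx)
  for (cc in counts) total[names(cc)] <- total[names(cc)] + as.integer(cc)
  total
}

#' Build the high-confidence RBP-transcript regulatory network
#'
#' An edge links an RBP to a transcript when the transcript is significantly
#' changed upon that RBP's knockdown (see [filter_significant()]) and at
#' least one of the RBP's binding peaks overlaps the transcript. By default
#' peaks must overlap exonic intervals (binding on the mature transcript);
#' `overlap = "span"` relaxes this to the full transcript locus. Peaks that
#' carry a strand are matched same-strand; unstranded peaks match either
#' strand.
#'
#' @param de_set named list (by RBP id) of DE data.frames with columns
#'   `transcript_id`, `log2fc`, `fdr`.
#' @param peak_set named list (by RBP id) of peak `GRanges` (or data.frames
#'   with chrom/start/end/strand).
#' @param models named list of [transcript_model()]s covering the
#'   transcripts.
#' @param fc_threshold,fdr_threshold significance thresholds passed to
#'   [filter_significant()].
#' @param overlap `"exon"` (default) or `"span"`.
#' @return data.frame of edges: `rbp_id`, `transcript_id`, `direction`
#'   (`up`/`down`, the sign of change upon knockdown), `log2fc`, `fdr`,
#'   `n_supporting_peaks`.
#' @export
build_network <- function(de_set, peak_set, models,
                          fc_threshold = 1.5, fdr_threshold = 0.05,
                          overlap = c("exon", "span")) {
  overlap <- match.arg(overlap)
  target_gr <- if (overlap == "exon") exon_granges(models) else span_granges(models)
  orphan <- setdiff(names(peak_set), names(de_set))
  if (length(orphan))
    warning("RBPs with peaks but no DE table skipped: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  edges <- lapply(names(de_set), function(rbp) {
    sig <- filter_significant(de_set[[rbp]], fc_threshold, fdr_threshold)
    if (!nrow(sig)) return(NULL)
    peaks <- peak_set[[rbp]]
    if (is.null(peaks) || !length(peaks)) return(NULL)
    hits <- count_peak_hits(peaks_to_granges(peaks), target_gr)
    n_peaks <- hits[sig$transcript_id]
    n_peaks[is.na(n_peaks)] <- 0L
    keep <- n_peaks >= 1L
    if (!any(keep)) return(NULL)
    data.frame(rbp_id = rbp,
               transcript_id = sig$transcript_id[keep],
               direction = ifelse(sig$log2fc[keep] > 0, "up", "down"),
               log2fc = sig$log2fc[keep],
               fdr = sig$fdr[keep],
               n_supporting_peaks = as.integer(n_peaks[keep]),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(rbp_id = character(0), transcript_id = character(0),
                        direction = character(0), log2fc = numeric(0),
                        fdr = numeric(0), n_supporting_peaks = integer(0),
                        stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges
}

#' Summarize a regulatory network
#'
#' @param edges data.frame from [build_network()].
#' @return List with `per_rbp` (total/up/down edge counts per RBP),
#'   `per_transcript` (distinct regulating RBPs per transcript), and
#'   `degree_distribution` (table of per-transcript RBP counts).
#' @export
summarize_network <- function(edges) {
  if (!nrow(edges)) {
    return(list(
      per_rbp = data.frame(rbp_id = character(0), total = integer(0),
                           up = integer(0), down = integer(0)),
      per_transcript = data.frame(transcript_id = character(0),
                                  n_rbps = integer(0)),
      degree_distribution = table(integer(0))))
  }
  per_rbp <- do.call(rbind, lapply(split(edges, edges$rbp_id), function(e)
    data.frame(rbp_id = e$rbp_id[1], total = nrow(e),
               up = sum(e$direction == "up"),
               down = sum(e$direction == "down"),
               stringsAsFactors = FALSE)))
  rownames(per_rbp) <- NULL
  deg <- tapply(edges$rbp_id, edges$transcript_id,
                function(r) length(unique(r)))
  per_transcript <- data.frame(transcript_id = names(deg),
                               n_rbps = as.integer(deg),
                               stringsAsFactors = FALSE)
  rownames(per_transcript) <- NULL
  list(per_rbp = per_rbp, per_transcript = per_transcript,
       degree_distribution = table(per_transcript$n_rbps))
}

#' Count cell lines in which each gene is essential
#'
#' A gene is essential in a cell line when its CRISPR dependency score is
#' strictly below the threshold (default -1).
#'
#' @param dep numeric matrix of dependency scores, rows = genes, columns =
#'   cell lines.
#' @param threshold essentiality cutoff (default -1, strict `<`).
#' @return data.frame: `gene_id`, `n_essential_cell_lines`.
#' @export
essentiality_summary <- function(dep, threshold = -1) {
  stopifnot(is.matrix(dep), is.numeric(dep))
  data.frame(gene_id = rownames(dep),
             n_essential_cell_lines = as.integer(rowSums(dep < threshold,
                                                         na.rm = TRUE)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a per-RBP differential-expression TSV
#'
#' @param path TSV with header columns `transcript_id`, `log2fc`, `pvalue`
#'   (optional), `fdr`.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "log2fc", "fdr") %in% names(de)))
  de
}
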