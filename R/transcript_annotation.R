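#' Build a transcript model
#'
#' A transcript model is a stranded exon chain on one chromosome, in 1-based
#' closed coordinates. Introns (splice junctions) and the transcription
#' start site (TSS) are derived: the TSS is the minimal coordinate on the
#' plus strand and the maximal coordinate on the minus strand.
#'
#' @param id transcript identifier.
#' @param gene_ids character vector of one or more gene labels.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), 1-based closed; rows may be
#'   given in any order but must not overlap.
#' @return A `TranscriptModel`: list with the fields above plus `introns`
#'   (matrix of intron start/end, zero rows for mono-exon models) and `tss`.
#' @export
transcript_model <- function(id, gene_ids, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]))
    stop("exon end < start in transcript ", id, call. = FALSE)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping or unsorted exons in transcript ", id, call. = FALSE)
  introns <- if (nrow(exons) > 1) {
    cbind(start = exons[-nrow(exons), 2] + 1, end = exons[-1, 1] - 1)
  } else {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  tss <- if (strand == "+") min(exons[, 1]) else max(exons[, 2])
  structure(list(id = id, gene_ids = gene_ids, chrom = chrom, strand = strand,
                 exons = exons, introns = introns, tss = tss),
            class = "TranscriptModel")
}

intron_chain <- function(model) {
  if (nrow(model$introns) == 0) return(character(0))
  paste(model$introns[, 1], model$introns[, 2], sep = "-")
}

model_span <- function(model) c(min(model$exons[, 1]), max(model$exons[, 2]))

#' Parse transcript models from a GTF file
#'
#' Reads `exon` features (1-based closed coordinates) and assembles one
#' model per `transcript_id`, deriving junctions and the strand-aware TSS.
#' Exon rows may appear in any file order.
#'
#' @param path GTF file with `transcript_id` and `gene_id` attributes on
#'   exon features.
#' @return Named list of [transcript_model()] objects.
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path, call. = FALSE)
  ids <- as.character(gr$transcript_id)
  models <- lapply(split(seq_along(gr), ids), function(idx) {
    sub <- gr[idx]
    transcript_model(
      id = as.character(sub$transcript_id[1]),
      gene_ids = unique(as.character(sub$gene_id)),
      chrom = as.character(GenomicRanges::seqnames(sub)[1]),
      strand = as.character(BiocGenerics::strand(sub)[1]),
      exons = cbind(BiocGenerics::start(sub), BiocGenerics::end(sub)))
  })
  models[order(names(models))]
}

#' Write transcript models to a GTF file
#'
#' Emits one `transcript` and per-exon `exon` features in 1-based closed
#' GTF coordinates.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    span <- model_span(m)
    feat <- rbind(c(span[1], span[2]), m$exons)
    data.frame(chrom = m$chrom,
               source = "txaxes",
               type = c("transcript", rep("exon", nrow(m$exons))),
               start = feat[, 1], end = feat[, 2],
               score = ".", strand = m$strand, frame = ".",
               attr = sprintf('gene_id "%s"; transcript_id "%s";',
                              m$gene_ids[1], m$id),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

exon_overlap_len <- function(a, b) {
  # total overlap between two exon matrices
  total <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi >= lo) total <- total + (hi - lo + 1)
  }
  total
}

exons_overlap <- function(a, b) exon_overlap_len(a, b) > 0

#' Classify a query transcript against a reference annotation
#'
#' Assigns exactly one category by the first matching rule, comparing
#' same-strand same-chromosome reference transcripts:
#' 1. `annotated_match` — intron chain identical to a reference transcript
#'    (mono-exon queries match a mono-exon reference they overlap);
#' 2. `contain_Ref` — the query chain strictly contains a reference
#'    transcript's full chain;
#' 3. `match_Refjunction` — shares at least one splice junction;
#' 4. `retain_Refintron` — a query exon fully spans a reference intron
#'    (retained intron);
#' 5. `overlap_Refexon` — exonic overlap with a reference exon;
#' 6. `within_Refintron` — query entirely inside one reference intron;
#' 7. `intergenic` — no overlap with any reference gene span on either
#'    strand.
#' A query overlapping a gene only on the opposite strand is classified by
#' re-trying rules 5 and 6 strand-agnostically, so every query receives a
#' category.
#'
#' @param query a [transcript_model()].
#' @param reference named list of reference [transcript_model()]s.
#' @return A one-row data.frame: `transcript_id`, `category`,
#'   `is_readthrough`, `overlapped_genes` (comma-separated exon-level
#'   same-strand gene hits).
#' @export
classify_against_reference <- function(query, reference) {
  same <- Filter(function(r) r$chrom == query$chrom && r$strand == query$strand,
                 reference)
  any_strand <- Filter(function(r) r$chrom == query$chrom, reference)
  qchain <- intron_chain(query)
  qspan <- model_span(query)

  category <- NULL
  if (length(qchain)) {
    for (r in same) if (identical(qchain, intron_chain(r))) {
      category <- "annotated_match"; break
    }
  } else {
    for (r in same) {
      if (nrow(r$exons) == 1 && exons_overlap(query$exons, r$exons)) {
        category <- "annotated_match"; break
      }
    }
  }
  if (is.null(category) && length(qchain) > 1) {
    for (r in same) {
      rchain <- intron_chain(r)
      if (length(rchain) && length(rchain) < length(qchain)) {
        # reference chain must be a contiguous sub-chain of the query chain
        hits <- which(qchain == rchain[1])
        for (h in hits) {
          if (h + length(rchain) - 1 <= length(qchain) &&
              identical(qchain[h:(h + length(rchain) - 1)], rchain)) {
            category <- "contain_Ref"; break
          }
        }
        if (!is.null(category)) break
      }
    }
  }
  if (is.null(category) && length(qchain)) {
    ref_junc <- unique(unlist(lapply(same, intron_chain)))
    if (any(qchain %in% ref_junc)) category <- "match_Refjunction"
  }
  if (is.null(category)) {
    for (r in same) {
      if (nrow(r$introns) == 0) next
      for (j in seq_len(nrow(r$introns))) {
        spans <- query$exons[, 1] < r$introns[j, 1] &
                 query$exons[, 2] > r$introns[j, 2]
        if (any(spans)) { category <- "retain_Refintron"; break }
      }
      if (!is.null(category)) break
    }
  }
  if (is.null(category)) {
    for (r in same) if (exons_overlap(query$exons, r$exons)) {
      category <- "overlap_Refexon"; break
    }
  }
  if (is.null(category)) {
    for (r in same) {
      if (nrow(r$introns) == 0) next
      inside <- r$introns[, 1] <= qspan[1] & qspan[2] <= r$introns[, 2]
      if (any(inside)) { category <- "within_Refintron"; break }
    }
  }
  if (is.null(category)) {
    overlaps_gene <- any(vapply(any_strand, function(r) {
      sp <- model_span(r)
      qspan[1] <= sp[2] && sp[1] <= qspan[2]
    }, logical(1)))
    if (!overlaps_gene) {
      category <- "intergenic"
    } else {
      # opposite-strand fallback keeps classification total
      for (r in any_strand) if (exons_overlap(query$exons, r$exons)) {
        category <- "overlap_Refexon"; break
      }
      if (is.null(category)) category <- "within_Refintron"
    }
  }
  genes <- overlapped_genes(query, reference)
  data.frame(transcript_id = query$id,
             category = category,
             is_readthrough = length(genes) >= 2,
             overlapped_genes = paste(genes, collapse = ","),
             stringsAsFactors = FALSE)
}

overlapped_genes <- function(query, reference) {
  # same-strand, exon-level gene hits, 5'-to-3'-agnostic genomic order
  hits <- character(0)
  starts <- numeric(0)
  for (r in reference) {
    if (r$chrom != query$chrom || r$strand != query$strand) next
    if (exons_overlap(query$exons, r$exons)) {
      for (g in r$gene_ids) {
        if (!g %in% hits) { hits <- c(hits, g); starts <- c(starts, model_span(r)[1]) }
      }
    }
  }
  hits[order(starts)]
}

#' Detect readthrough transcripts
#'
#' A readthrough transcript is one whose exons overlap exons of two or more
#' distinct same-strand reference genes.
#'
#' @param query a [transcript_model()].
#' @param reference named list of reference models.
#' @return Logical flag.
#' @export
detect_readthrough <- function(query, reference) {
  length(overlapped_genes(query, reference)) >= 2
}

#' Classify a set of query transcripts
#'
#' Vectorized driver over [classify_against_reference()].
#'
#' @param queries named list of query [transcript_model()]s.
#' @param reference named list of reference models.
#' @return data.frame, one row per query.
#' @export
classify_transcripts <- function(queries, reference) {
  do.call(rbind, lapply(queries, classify_against_reference,
                        reference = reference))
}

#' Assign gene-based transcript names
#'
#' Transcripts whose structure matches the reference (`annotated_match`) are
#' named `<gene>-a<k>`; all other gene-overlapping transcripts are named
#' `<gene>-u<k>`. Counters run per gene and per class, starting at 1 in
#' ascending genomic start order. The host gene is determined by same-strand
#' gene-span overlap (so intronic transcripts are named by their host
#' gene); transcripts overlapping no gene keep their input id. Multi-gene
#' (readthrough) transcripts are named by their first overlapped gene in
#' genomic order.
#'
#' @param classified data.frame from [classify_transcripts()].
#' @param queries the named list of query models used for classification
#'   (supplies genomic start coordinates for counter ordering).
#' @param reference named list of reference models (supplies gene spans).
#' @return `classified` with an `assigned_name` column appended.
#' @export
assign_names <- function(classified, queries, reference) {
  gene_span <- list()
  for (r in reference) {
    sp <- model_span(r)
    for (g in r$gene_ids) {
      cur <- gene_span[[g]]
      gene_span[[g]] <- if (is.null(cur))
        list(chrom = r$chrom, strand = r$strand, start = sp[1], end = sp[2])
      else
        list(chrom = cur$chrom, strand = cur$strand,
             start = min(cur$start, sp[1]), end = max(cur$end, sp[2]))
    }
  }
  host_gene <- function(q) {
    hits <- character(0); starts <- numeric(0)
    for (g in names(gene_span)) {
      s <- gene_span[[g]]
      sp <- model_span(q)
      if (s$chrom == q$chrom && s$strand == q$strand &&
          sp[1] <= s$end && s$start <= sp[2]) {
        hits <- c(hits, g); starts <- c(starts, s$start)
      }
    }
    if (!length(hits)) return(NA_character_)
    hits[order(starts)][1]
  }
  starts <- vapply(classified$transcript_id,
                   function(id) model_span(queries[[id]])[1], numeric(1))
  cls <- ifelse(classified$category == "annotated_match", "a", "u")
  gene <- vapply(classified$transcript_id,
                 function(id) host_gene(queries[[id]]), character(1))
  name <- classified$transcript_id
  ord <- order(starts)
  counters <- new.env(parent = emptyenv())
  for (i in ord) {
    if (is.na(gene[i])) next
    key <- paste0(gene[i], ":", cls[i])
    k <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
    counters[[key]] <- k
    name[i] <- paste0(gene[i], "-", cls[i], k)
  }
  classified$assigned_name <- name
  classified
}

#' Score transcription evidence around transcript start sites
#'
#' A transcript has transcription evidence when a CAGE peak or an active
#' chromatin-state peak falls within 500 nt of its TSS. The window is
#' closed: a peak whose nearest base is exactly `window` nt from the TSS
#' counts; one base further does not. Any overlap of the peak interval with
#' the window counts.
#'
#' @param models named list of [transcript_model()]s.
#' @param cage_peaks,chromatin_peaks `GRanges` of peaks (e.g. from
#'   [read_bed()]), or `NULL` for none.
#' @param window half-width of the TSS window in nt (default 500).
#' @return data.frame: `transcript_id`, `has_cage`, `has_chromatin`,
#'   `label` in `both`/`cage_only`/`chromatin_only`/`none`.
#' @export
tss_evidence <- function(models, cage_peaks, chromatin_peaks, window = 500) {
  tss_gr <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = pmax(1, vapply(models, `[[`, numeric(1), "tss") - window),
      end = vapply(models, `[[`, numeric(1), "tss") + window))
  check_chroms <- function(peaks, what) {
    if (is.null(peaks) || !length(peaks)) return(invisible())
    shared <- intersect(as.character(unique(GenomicRanges::seqnames(tss_gr))),
                        as.character(unique(GenomicRanges::seqnames(peaks))))
    if (!length(shared)) {
      counts <- table(as.character(GenomicRanges::seqnames(peaks)))
      warning("no shared chromosome names with ", what, " peaks (",
              paste(names(counts), counts, sep = ":", collapse = ", "), ")",
              call. = FALSE)
    }
  }
  hit <- function(peaks) {
    if (is.null(peaks) || !length(peaks)) return(rep(FALSE, length(tss_gr)))
    # disjoint seqlevel sets are already reported by check_chroms
    suppressWarnings(IRanges::overlapsAny(tss_gr, peaks, ignore.strand = TRUE))
  }
  check_chroms(cage_peaks, "CAGE")
  check_chroms(chromatin_peaks, "chromatin-state")
  has_cage <- hit(cage_peaks)
  has_chromatin <- hit(chromatin_peaks)
  label <- ifelse(has_cage & has_chromatin, "both",
           ifelse(has_cage, "cage_only",
           ifelse(has_chromatin, "chromatin_only", "none")))
  data.frame(transcript_id = vapply(models, `[[`, character(1), "id"),
             has_cage = has_cage, has_chromatin = has_chromatin,
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a BED peak file
#'
#' BED intervals are 0-based half-open on disk; the returned `GRanges` uses
#' the 1-based closed convention, so round-tripping through [write_bed()]
#' is lossless.
#'
#' @param path BED file (>= 3 columns).
#' @return A `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "bed")

#' Write peaks to a BED file
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
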