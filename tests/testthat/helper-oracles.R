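# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (plain loops, no shared code with R/).

# direct-summation Shannon specificity score for one ratio vector
entropy_score_oracle <- function(p, N = length(p)) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  log2(N) - h
}

# brute-force double filter for the regulatory network: significance by the
# printed thresholds, plus >=1 peak overlapping an exon of the transcript
# (same strand when the peak is stranded), via plain interval arithmetic
brute_force_network <- function(de_set, peak_set, models,
                                fc_threshold = 1.5, fdr_threshold = 0.05) {
  out <- list()
  for (rbp in names(de_set)) {
    de <- de_set[[rbp]]
    peaks <- peak_set[[rbp]]
    if (is.null(peaks)) next
    pk <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(peaks)),
      start = BiocGenerics::start(peaks),
      end = BiocGenerics::end(peaks),
      strand = as.character(BiocGenerics::strand(peaks)),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(de))) {
      if (!(abs(de$log2fc[i]) > log2(fc_threshold) &&
            de$fdr[i] < fdr_threshold)) next
      m <- models[[de$transcript_id[i]]]
      if (is.null(m)) next
      n_hit <- 0
      for (j in seq_len(nrow(pk))) {
        if (pk$chrom[j] != m$chrom) next
        if (pk$strand[j] %in% c("+", "-") && pk$strand[j] != m$strand) next
        hit <- FALSE
        for (e in seq_len(nrow(m$exons))) {
          if (pk$start[j] <= m$exons[e, 2] && m$exons[e, 1] <= pk$end[j]) {
            hit <- TRUE
          }
        }
        if (hit) n_hit <- n_hit + 1
      }
      if (n_hit >= 1) {
        out[[length(out) + 1L]] <- data.frame(
          rbp_id = rbp, transcript_id = de$transcript_id[i],
          direction = if (de$log2fc[i] > 0) "up" else "down",
          n_supporting_peaks = n_hit, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(rbp_id = character(0), transcript_id = character(0),
                      direction = character(0),
                      n_supporting_peaks = integer(0)))
  do.call(rbind, out)
}

# brute-force nested-loop relational join on transcript_id
brute_force_axes <- function(edges, associations) {
  out <- list()
  for (i in seq_len(nrow(edges))) for (j in seq_len(nrow(associations))) {
    if (edges$transcript_id[i] == associations$transcript_id[j]) {
      out[[length(out) + 1L]] <- data.frame(
        rbp_id = edges$rbp_id[i],
        transcript_id = edges$transcript_id[i],
        drug_id = associations$drug_id[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(rbp_id = character(0), transcript_id = character(0),
                      drug_id = character(0)))
  do.call(rbind, out)
}

axis_key <- function(df) sort(paste(df$rbp_id, df$transcript_id, df$drug_id))
edge_key <- function(df) sort(paste(df$rbp_id, df$transcript_id))

# random DE/peak/model fixture for network equivalence tests
random_network_fixture <- function(n_rbps, n_transcripts, seed) {
  set.seed(seed)
  tx <- sprintf("T%03d", seq_len(n_transcripts))
  models <- toy_models(tx)
  de_set <- lapply(seq_len(n_rbps), function(r) {
    data.frame(transcript_id = tx,
               log2fc = round(stats::rnorm(n_transcripts, 0, 1.2), 3),
               fdr = round(stats::runif(n_transcripts), 3),
               stringsAsFactors = FALSE)
  })
  names(de_set) <- sprintf("R%02d", seq_len(n_rbps))
  peak_set <- lapply(names(de_set), function(r) {
    hit_tx <- sample(tx, n_transcripts %/% 3)
    grs <- lapply(hit_tx, function(t) {
      m <- models[[t]]
      e <- m$exons[sample.int(nrow(m$exons), 1), ]
      # half the peaks intronic/flanking to exercise the exon-only policy
      if (stats::runif(1) < 0.5) {
        GenomicRanges::GRanges(m$chrom,
                               IRanges::IRanges(e[1] + 5, e[1] + 25),
                               strand = m$strand)
      } else {
        GenomicRanges::GRanges(m$chrom,
                               IRanges::IRanges(e[2] + 5, e[2] + 25),
                               strand = m$strand)
      }
    })
    do.call(c, grs)
  })
  names(peak_set) <- names(de_set)
  list(de_set = de_set, peak_set = peak_set, models = models)
}

# small deterministic atlas for IO / filter tests
tiny_atlas <- function() {
  m <- matrix(c(5, 0.1, 0, 2,
                1, 0.05, 0, 3,
                4, 0.1, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("tA", "tB", "tC"),
                              c("c1", "c2", "c3", "c4")))
  expression_atlas(m, c(c1 = "lung", c2 = "lung", c3 = "skin", c4 = "skin"))
}
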