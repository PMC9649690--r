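#' Configuration for the synthetic expression atlas
#'
#' Defaults describe a desk-scale pan-cancer atlas: 2,000 transcripts over
#' 110 cell lines spread evenly across 22 lineages, with 200 planted
#' lineage-specific transcripts whose home lineage carries 80% of their
#' lineage-summed expression. Baseline TPM is lognormal with a per-cell
#' Bernoulli dropout, reproducing the sparse, low-expression character of
#' transcript-level TPM matrices without modeling read counts.
#'
#' @param n_transcripts,n_cell_lines,n_lineages atlas dimensions; every
#'   lineage must receive at least 2 cell lines.
#' @param n_planted_specific number of planted lineage-specific transcripts.
#' @param specific_ratio target share of a planted transcript's
#'   lineage-summed expression in its home lineage, in (0, 1].
#' @param baseline_log_mean,baseline_log_sd lognormal TPM parameters
#'   (natural-log scale).
#' @param dropout_prob per-cell probability of an exact zero.
#' @param seed integer seed.
#' @return A validated `AtlasSimConfig` list.
#' @export
atlas_sim_config <- function(n_transcripts = 2000, n_cell_lines = 110,
                             n_lineages = 22, n_planted_specific = 200,
                             specific_ratio = 0.8, baseline_log_mean = 0,
                             baseline_log_sd = 1, dropout_prob = 0.3,
                             seed = 1) {
  cfg <- list(n_transcripts = n_transcripts, n_cell_lines = n_cell_lines,
              n_lineages = n_lineages,
              n_planted_specific = n_planted_specific,
              specific_ratio = specific_ratio,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dropout_prob = dropout_prob, seed = seed)
  if (cfg$n_planted_specific > cfg$n_transcripts)
    stop("n_planted_specific exceeds n_transcripts", call. = FALSE)
  if (cfg$n_lineages < 2) stop("need at least 2 lineages", call. = FALSE)
  if (cfg$n_cell_lines < 2 * cfg$n_lineages)
    stop("each lineage needs at least 2 cell lines", call. = FALSE)
  if (cfg$specific_ratio <= 0 || cfg$specific_ratio > 1)
    stop("specific_ratio must be in (0, 1]", call. = FALSE)
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]", call. = FALSE)
  cfg
}

#' Simulate a transcript expression atlas with planted specificity
#'
#' Draws a lognormal TPM baseline, multiplies each cell by an independent
#' Bernoulli(1 - dropout) indicator, and boosts each planted transcript's
#' home-lineage cells by the factor that sets its expected home-lineage
#' expression share to `specific_ratio`. Non-planted transcripts have
#' exchangeable lineage means.
#'
#' @param cfg an [atlas_sim_config()].
#' @return List with `atlas` (an [expression_atlas()]) and `truth` (list
#'   with `specific_transcripts`, a named character vector
#'   transcript -> home lineage).
#' @export
simulate_expression_atlas <- function(cfg) {
  cfg <- do.call(atlas_sim_config, cfg)
  rng <- local_rng(cfg$seed)
  tx <- sprintf("TX%05d", seq_len(cfg$n_transcripts))
  cl <- sprintf("CL%04d", seq_len(cfg$n_cell_lines))
  lineages <- sprintf("lineage%02d", seq_len(cfg$n_lineages))
  lineage_of <- stats::setNames(
    lineages[rep_len(seq_len(cfg$n_lineages), cfg$n_cell_lines)], cl)
  base <- rng(matrix(
    stats::rlnorm(cfg$n_transcripts * cfg$n_cell_lines,
                  cfg$baseline_log_mean, cfg$baseline_log_sd),
    cfg$n_transcripts, cfg$n_cell_lines, dimnames = list(tx, cl)))
  planted <- tx[seq_len(cfg$n_planted_specific)]
  home <- rng(sample(lineages, cfg$n_planted_specific, replace = TRUE))
  names(home) <- planted
  if (cfg$n_planted_specific > 0 && cfg$specific_ratio < 1) {
    # boost f solves f*m / (f*m + (N-1)*m) = specific_ratio for equal means m
    f <- cfg$specific_ratio * (cfg$n_lineages - 1) / (1 - cfg$specific_ratio)
    for (t in planted) {
      cols <- lineage_of[cl] == home[t]
      base[t, cols] <- base[t, cols] * f
    }
  } else if (cfg$n_planted_specific > 0) {
    for (t in planted) base[t, lineage_of[cl] != home[t]] <- 0
  }
  if (cfg$dropout_prob > 0) {
    keep <- rng(matrix(
      stats::rbinom(length(base), 1, 1 - cfg$dropout_prob),
      nrow(base), ncol(base)))
    base <- base * keep
  }
  list(atlas = expression_atlas(base, lineage_of),
       truth = list(specific_transcripts = home))
}

#' Configuration for the synthetic drug-response panel
#'
#' @param n_drugs number of drugs.
#' @param n_driver_transcripts_per_drug planted driver transcripts per drug.
#' @param effect_size coefficient on each driver's standardized expression
#'   (the elastic-net-scale effect).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param auc_center,auc_scale affine placement of the AUC values.
#' @param seed integer seed.
#' @return A validated `DrugSimConfig` list.
#' @export
drug_sim_config <- function(n_drugs = 3, n_driver_transcripts_per_drug = 5,
                            effect_size = 1.0, noise_sd = 1.0,
                            auc_center = 10, auc_scale = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  list(n_drugs = n_drugs,
       n_driver_transcripts_per_drug = n_driver_transcripts_per_drug,
       effect_size = effect_size, noise_sd = noise_sd,
       auc_center = auc_center, auc_scale = auc_scale, seed = seed)
}

#' Simulate a drug-response AUC panel driven by planted transcripts
#'
#' For each drug, samples driver transcripts from those passing the strict
#' 20% prevalence filter, assigns each a random sign, and sets
#' `AUC = auc_center + auc_scale * (sum(effect_size * sign * z(driver)) +
#' noise)` where `z()` is the per-transcript standardization used
#' downstream and the noise is Gaussian with sd `noise_sd`.
#'
#' @param atlas an [expression_atlas()].
#' @param cfg a [drug_sim_config()].
#' @return List with `auc` (cell line x drug matrix) and `truth` (data.frame
#'   `drug_id`, `transcript_id`, `sign`).
#' @export
simulate_drug_response <- function(atlas, cfg) {
  cfg <- do.call(drug_sim_config, cfg)
  stopifnot(inherits(atlas, "ExpressionAtlas"), nrow(atlas$values) > 0)
  # strict drug-mode prevalence: > 0.1 TPM in at least 20% of cell lines
  pool <- rownames(atlas$values)[rowMeans(atlas$values > 0.1) >= 0.2]
  pool <- pool[apply(atlas$values[pool, , drop = FALSE], 1, stats::sd) > 0]
  if (length(pool) < cfg$n_driver_transcripts_per_drug)
    stop("driver pool empty or too small after prevalence filter",
         call. = FALSE)
  rng <- local_rng(cfg$seed)
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  n <- ncol(atlas$values)
  auc <- matrix(NA_real_, n, cfg$n_drugs,
                dimnames = list(colnames(atlas$values), drugs))
  truth <- list()
  for (d in drugs) {
    drivers <- rng(sample(pool, cfg$n_driver_transcripts_per_drug))
    signs <- rng(sample(c(-1, 1), length(drivers), replace = TRUE))
    Z <- scale(t(atlas$values[drivers, , drop = FALSE]))
    signal <- as.numeric(Z %*% (cfg$effect_size * signs))
    noise <- if (cfg$noise_sd > 0) rng(stats::rnorm(n, 0, cfg$noise_sd)) else 0
    auc[, d] <- cfg$auc_center + cfg$auc_scale * (signal + noise)
    truth[[d]] <- data.frame(drug_id = d, transcript_id = drivers,
                             sign = signs, stringsAsFactors = FALSE)
  }
  list(auc = auc, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Configuration for the synthetic regulome
#'
#' @param n_rbps number of RBPs.
#' @param n_regulated_per_rbp planted regulated transcripts per RBP.
#' @param frac_bound_of_regulated share of each RBP's regulated transcripts
#'   that also receive a binding peak, in \[0, 1\].
#' @param lfc_effect absolute log2 fold change of planted transcripts; must
#'   clear the downstream |fold change| > 1.5 filter, i.e. exceed
#'   log2(1.5), unless deliberately set below it.
#' @param null_fdr_floor minimum FDR of non-regulated transcripts.
#' @param n_random_peaks_per_rbp decoy peaks placed in random exons.
#' @param seed integer seed.
#' @return A validated `RegulomeSimConfig` list.
#' @export
regulome_sim_config <- function(n_rbps = 5, n_regulated_per_rbp = 20,
                                frac_bound_of_regulated = 0.8,
                                lfc_effect = 1.5, null_fdr_floor = 0.2,
                                n_random_peaks_per_rbp = 10, seed = 1) {
  if (frac_bound_of_regulated < 0 || frac_bound_of_regulated > 1)
    stop("frac_bound_of_regulated must be in [0, 1]", call. = FALSE)
  list(n_rbps = n_rbps, n_regulated_per_rbp = n_regulated_per_rbp,
       frac_bound_of_regulated = frac_bound_of_regulated,
       lfc_effect = lfc_effect, null_fdr_floor = null_fdr_floor,
       n_random_peaks_per_rbp = n_random_peaks_per_rbp, seed = seed)
}

#' Simulate knockdown DE tables and binding peaks with planted regulation
#'
#' Each RBP receives a DE table in which planted transcripts change by
#' `lfc_effect` in log2 units (random direction) at FDR below 0.05, while
#' null transcripts sit below the fold-change threshold with FDR at or
#' above `null_fdr_floor`. A binding peak is placed inside an exon of
#' `frac_bound_of_regulated` of each RBP's planted transcripts; decoy peaks
#' land in exons of random other transcripts.
#'
#' @param transcript_ids transcripts to cover in every DE table.
#' @param cfg a [regulome_sim_config()].
#' @param models named list of [transcript_model()]s covering
#'   `transcript_ids` (supplies exon intervals for peak placement).
#' @return List: `de_set` (named list of DE data.frames), `peak_set` (named
#'   list of peak `GRanges`), `truth` (data.frame `rbp_id`,
#'   `transcript_id`, `direction`, `bound`).
#' @export
simulate_regulome <- function(transcript_ids, cfg, models) {
  cfg <- do.call(regulome_sim_config, cfg)
  stopifnot(all(transcript_ids %in% names(models)),
            cfg$n_regulated_per_rbp <= length(transcript_ids))
  rng <- local_rng(cfg$seed)
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbps))
  de_set <- list(); peak_set <- list(); truth <- list()
  for (rbp in rbps) {
    reg <- rng(sample(transcript_ids, cfg$n_regulated_per_rbp))
    dir_up <- rng(sample(c(TRUE, FALSE), length(reg), replace = TRUE))
    lfc <- rng(stats::runif(length(transcript_ids), -0.3, 0.3))
    names(lfc) <- transcript_ids
    lfc[reg] <- ifelse(dir_up, cfg$lfc_effect, -cfg$lfc_effect)
    fdr <- rng(stats::runif(length(transcript_ids), cfg$null_fdr_floor, 1))
    names(fdr) <- transcript_ids
    fdr[reg] <- rng(stats::runif(length(reg), 0, 0.049))
    de_set[[rbp]] <- data.frame(transcript_id = transcript_ids,
                                log2fc = unname(lfc[transcript_ids]),
                                pvalue = unname(fdr[transcript_ids]) / 2,
                                fdr = unname(fdr[transcript_ids]),
                                stringsAsFactors = FALSE)
    n_bound <- round(cfg$frac_bound_of_regulated * length(reg))
    bound <- if (n_bound > 0) rng(sample(reg, n_bound)) else character(0)
    decoys <- rng(sample(setdiff(transcript_ids, reg),
                         min(cfg$n_random_peaks_per_rbp,
                             length(transcript_ids) - length(reg))))
    peak_in_exon <- function(tx) {
      m <- models[[tx]]
      e <- m$exons[rng(sample.int(nrow(m$exons), 1)), ]
      mid <- floor((e[1] + e[2]) / 2)
      GenomicRanges::GRanges(m$chrom,
                             IRanges::IRanges(max(e[1], mid - 10),
                                              min(e[2], mid + 10)),
                             strand = m$strand)
    }
    peaks <- lapply(c(bound, decoys), peak_in_exon)
    peak_set[[rbp]] <- if (length(peaks)) do.call(c, peaks) else
      GenomicRanges::GRanges()
    truth[[rbp]] <- data.frame(rbp_id = rbp, transcript_id = reg,
                               direction = ifelse(dir_up, "up", "down"),
                               bound = reg %in% bound,
                               stringsAsFactors = FALSE)
  }
  list(de_set = de_set, peak_set = peak_set,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate toy transcript models spanning all classification categories
#'
#' Builds a small reference annotation (two adjacent same-strand genes plus
#' a minus-strand gene) and one query transcript per classification
#' category — exact intron-chain match, chain containment, junction
#' sharing, intron retention, exon overlap, intronic containment, and
#' intergenic — plus a readthrough query spanning both plus-strand genes,
#' and CAGE / chromatin-state peaks placed at 0, exactly 500, and 501 nt
#' from chosen TSSs.
#'
#' @param chrom chromosome name for all models (default `"chr1"`).
#' @return List: `reference` and `queries` (named lists of
#'   [transcript_model()]s), `truth` (data.frame `transcript_id`,
#'   `category`, `is_readthrough`), `cage_peaks`, `chromatin_peaks`
#'   (`GRanges`), `evidence_truth` (data.frame `transcript_id`, `label`).
#' @export
simulate_annotation <- function(chrom = "chr1") {
  ref <- list(
    # gene A: 3 exons on +, TSS 1000
    refA = transcript_model("refA", "GENEA", chrom, "+",
                            rbind(c(1000, 1200), c(1500, 1700), c(2000, 2200))),
    # gene B: 2 exons on +, downstream of A
    refB = transcript_model("refB", "GENEB", chrom, "+",
                            rbind(c(5000, 5200), c(5500, 5700))),
    # gene C on -, TSS = 9200
    refC = transcript_model("refC", "GENEC", chrom, "-",
                            rbind(c(8000, 8200), c(9000, 9200))),
    # gene D on +, no peaks anywhere near its TSS (15000)
    refD = transcript_model("refD", "GENED", chrom, "+",
                            rbind(c(15000, 15200), c(15400, 15600))))
  queries <- list(
    # identical intron chain to refA (differing ends still match the chain)
    q_match = transcript_model("q_match", "GENEA", chrom, "+",
                               rbind(c(950, 1200), c(1500, 1700), c(2000, 2250))),
    # chain strictly containing refB's full chain
    q_contain = transcript_model("q_contain", "GENEB", chrom, "+",
                                 rbind(c(4800, 4900), c(4950, 5200),
                                       c(5500, 5700))),
    # shares refA's first junction only
    q_junction = transcript_model("q_junction", "GENEA", chrom, "+",
                                  rbind(c(1100, 1200), c(1500, 1600),
                                        c(1800, 1900))),
    # single exon spanning refA's first intron and its flanks
    q_retain = transcript_model("q_retain", "GENEA", chrom, "+",
                                rbind(c(1100, 1800))),
    # mono-exon overlapping refA's last exon, no junctions
    q_overlap = transcript_model("q_overlap", "GENEA", chrom, "+",
                                 rbind(c(2100, 2400))),
    # mono-exon strictly inside refA's second intron (1701..1999)
    q_within = transcript_model("q_within", "GENEA", chrom, "+",
                                rbind(c(1750, 1950))),
    # far from every gene
    q_intergenic = transcript_model("q_intergenic", NA_character_, chrom, "+",
                                    rbind(c(20000, 20500))),
    # readthrough: exons overlap refA and refB exons, shares a junction
    q_readthrough = transcript_model("q_readthrough", "GENEA", chrom, "+",
                                     rbind(c(1000, 1200), c(1500, 1700),
                                           c(5000, 5200))))
  truth <- data.frame(
    transcript_id = c("q_match", "q_contain", "q_junction", "q_retain",
                      "q_overlap", "q_within", "q_intergenic",
                      "q_readthrough"),
    category = c("annotated_match", "contain_Ref", "match_Refjunction",
                 "retain_Refintron", "overlap_Refexon", "within_Refintron",
                 "intergenic", "match_Refjunction"),
    is_readthrough = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  # TSSs: refA 1000 (+), refB 5000 (+), refC 9200 (-), refD 15000 (+).
  # CAGE: on refA's TSS; nearest base exactly 500 nt from refB's TSS
  # (base 4500, the inclusive window edge).
  cage <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = c(995, 4480), end = c(1005, 4500)))
  # chromatin: near refA's TSS; nearest base 501 nt from refB's TSS
  # (base 4499, one past the window); on refC's TSS.
  chromatin <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = c(900, 4480, 9150), end = c(950, 4499, 9250)))
  evidence_truth <- data.frame(
    transcript_id = c("refA", "refB", "refC", "refD"),
    label = c("both", "cage_only", "chromatin_only", "none"),
    stringsAsFactors = FALSE)
  list(reference = ref, queries = queries, truth = truth,
       cage_peaks = cage, chromatin_peaks = chromatin,
       evidence_truth = evidence_truth)
}

#' Simple toy transcript models for network fixtures
#'
#' Lays out `n` single- or two-exon transcripts end to end on one
#' chromosome, for use as peak-placement substrate in regulome simulations
#' and network tests.
#'
#' @param transcript_ids character vector of ids.
#' @param chrom chromosome name.
#' @param exon_len,gap exon length and inter-transcript gap in nt.
#' @return Named list of [transcript_model()]s (each two exons separated by
#'   a short intron, alternating strands).
#' @export
toy_models <- function(transcript_ids, chrom = "chr1", exon_len = 200,
                       gap = 300) {
  models <- list()
  pos <- 1000
  for (i in seq_along(transcript_ids)) {
    id <- transcript_ids[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    exons <- rbind(c(pos, pos + exon_len - 1),
                   c(pos + exon_len + 100, pos + 2 * exon_len + 99))
    models[[id]] <- transcript_model(id, paste0("G_", id), chrom, strand, exons)
    pos <- pos + 2 * exon_len + 100 + gap
  }
  models
}
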