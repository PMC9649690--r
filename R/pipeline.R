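#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in dependency order — simulate inputs, prevalence
#' filtering and lineage-specificity calling, transcript classification and
#' TSS evidence, regulatory-network construction, drug association, and
#' axis integration — writing each stage's tables plus a JSON manifest of
#' parameters, seeds, and per-stage row counts into `out_dir`. A rerun with
#' the same config and seed reproduces the output tables byte for byte.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   See the bundled demo: `system.file("extdata", "demo_config.yaml",
#'   package = "txaxes")`. Recognized top-level keys: `seed`, `out_dir`,
#'   `stages` (character vector of stage names to run; default all),
#'   `atlas`, `drugs`, `regulome` (simulator configs), and `thresholds`
#'   (`min_tpm`, `prevalence_fraction`, `fc`, `fdr`, `rho_min`, `fdr_max`,
#'   `bootstrap_B`, `score_threshold`, `tss_window`).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out_dir <- if (!is.null(out_dir)) out_dir else cfg$out_dir
  if (is.null(out_dir)) stop("no out_dir given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  if (is.null(stages))
    stages <- c("simulate", "specificity", "annotate", "network",
                "drugassoc", "axes")
  th <- utils::modifyList(
    list(min_tpm = 0.1, prevalence_fraction = 0.2, fc = 1.5, fdr = 0.05,
         rho_min = 0.2, fdr_max = 0.05, bootstrap_B = 1000,
         score_threshold = 0.7, tss_window = 500),
    if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  manifest <- list(package_version = as.character(utils::packageVersion("txaxes")),
                   seed = seed, thresholds = th, stages = stages,
                   counts = list())
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nrow(df)
  }
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name, ...) {
    message(sprintf("[%6.1fs] %s %s", proc.time()[["elapsed"]] - t0, name,
                    paste(..., collapse = " ")))
  }

  # -- simulate ---------------------------------------------------------
  atlas_cfg <- utils::modifyList(atlas_sim_config(seed = derive_seed(seed, "atlas")),
                                 if (is.null(cfg$atlas)) list() else cfg$atlas)
  sim <- simulate_expression_atlas(atlas_cfg)
  atlas <- sim$atlas
  models <- toy_models(rownames(atlas$values))
  drug_cfg <- utils::modifyList(drug_sim_config(seed = derive_seed(seed, "drugs")),
                                if (is.null(cfg$drugs)) list() else cfg$drugs)
  dsim <- simulate_drug_response(atlas, drug_cfg)
  reg_cfg <- utils::modifyList(regulome_sim_config(seed = derive_seed(seed, "regulome")),
                               if (is.null(cfg$regulome)) list() else cfg$regulome)
  rsim <- simulate_regulome(rownames(atlas$values), reg_cfg, models)
  if ("simulate" %in% stages) {
    write_expression(atlas, file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "lineages.tsv"))
    jsonlite::write_json(
      list(specific_transcripts = as.list(sim$truth$specific_transcripts),
           drug_drivers = dsim$truth, regulated = rsim$truth),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    manifest$counts$simulate <- list(
      transcripts = nrow(atlas$values), cell_lines = ncol(atlas$values),
      drugs = ncol(dsim$auc), rbps = length(rsim$de_set))
    log_stage("simulate", nrow(atlas$values), "transcripts")
  }

  # -- specificity ------------------------------------------------------
  filtered <- prevalence_filter(atlas, th$min_tpm, min_count = 1,
                                mode = "inclusive")
  if ("specificity" %in% stages) {
    prof <- aggregate_by_lineage(filtered)
    calls <- call_lineage_specific(specificity_scores(prof))
    manifest$counts$specificity <- list(
      atlas_filter_kept = nrow(filtered$values),
      atlas_filter_removed = nrow(atlas$values) - nrow(filtered$values),
      scored = sum(!calls$undefined),
      called_specific = sum(calls$is_specific),
      rows = tsv(calls, "specificity.tsv"))
    log_stage("specificity", sum(calls$is_specific), "lineage-specific calls")
  }

  # -- annotate ---------------------------------------------------------
  if ("annotate" %in% stages) {
    ann <- simulate_annotation()
    classified <- classify_transcripts(ann$queries, ann$reference)
    classified <- assign_names(classified, ann$queries, ann$reference)
    evidence <- tss_evidence(ann$reference, ann$cage_peaks,
                             ann$chromatin_peaks, th$tss_window)
    manifest$counts$annotate <- list(
      rows = tsv(classified, "classification.tsv"),
      evidence_rows = tsv(evidence, "tss_evidence.tsv"))
    log_stage("annotate", nrow(classified), "queries classified")
  }

  # -- network ----------------------------------------------------------
  edges <- NULL
  if (any(c("network", "axes") %in% stages)) {
    edges <- build_network(rsim$de_set, rsim$peak_set, models,
                           fc_threshold = th$fc, fdr_threshold = th$fdr)
    if ("network" %in% stages) {
      summ <- summarize_network(edges)
      manifest$counts$network <- list(
        edges = tsv(edges, "edges.tsv"),
        rbps = nrow(summ$per_rbp),
        regulated_transcripts = nrow(summ$per_transcript))
      tsv(summ$per_rbp, "network_per_rbp.tsv")
      log_stage("network", nrow(edges), "edges")
    }
  }

  # -- drugassoc --------------------------------------------------------
  assoc <- NULL
  if (any(c("drugassoc", "axes") %in% stages)) {
    drug_atlas <- prevalence_filter(filtered, th$min_tpm,
                                    min_fraction = th$prevalence_fraction,
                                    mode = "strict")
    da <- associate_drugs(drug_atlas, dsim$auc,
                          rho_min = th$rho_min, fdr_max = th$fdr_max,
                          B = th$bootstrap_B,
                          score_threshold = th$score_threshold,
                          seed = derive_seed(seed, "assoc"))
    assoc <- da$associations
    if ("drugassoc" %in% stages) {
      manifest$counts$drugassoc <- list(
        prefilter_pairs = nrow(da$prefilter),
        prefilter_pass = sum(da$prefilter$pass),
        scored_pairs = nrow(da$scores),
        associations = tsv(assoc, "associations.tsv"))
      tsv(da$prefilter, "prefilter.tsv")
      log_stage("drugassoc", nrow(assoc), "called associations")
    }
  }

  # -- axes -------------------------------------------------------------
  if ("axes" %in% stages) {
    if (is.null(edges) || is.null(assoc))
      stop("axes stage requires network and drugassoc outputs", call. = FALSE)
    axes <- suppressWarnings(build_axes(edges, assoc))
    manifest$counts$axes <- list(axes = tsv(axes, "axes.tsv"))
    summary_json <- summarize_axes(axes)
    jsonlite::write_json(summary_json, file.path(out_dir, "axes_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("axes", nrow(axes), "axes")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
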