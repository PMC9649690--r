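test_that("atlas simulator is seeded, dimensioned, and degenerate-safe", {
  cfg <- list(n_transcripts = 400, n_cell_lines = 66, n_lineages = 22,
              n_planted_specific = 40, specific_ratio = 0.8, seed = 7)
  s1 <- simulate_expression_atlas(cfg)
  expect_equal(dim(s1$atlas$values), c(400, 66))
  expect_equal(length(s1$truth$specific_transcripts), 40)
  expect_equal(length(unique(s1$atlas$lineage_of)), 22)
  s2 <- simulate_expression_atlas(cfg)
  expect_identical(s1$atlas$values, s2$atlas$values)
  expect_identical(s1$truth, s2$truth)

  z <- simulate_expression_atlas(c(cfg, list(dropout_prob = 1)))
  expect_true(all(z$atlas$values == 0))

  expect_error(simulate_expression_atlas(list(n_transcripts = 10,
                                              n_planted_specific = 11)),
               "exceeds")
  expect_error(simulate_expression_atlas(list(n_lineages = 1)), "lineages")
  expect_error(simulate_expression_atlas(list(n_cell_lines = 10,
                                              n_lineages = 10)),
               "at least 2 cell lines")
})

test_that("planted transcripts concentrate expression in their home lineage", {
  sim <- simulate_expression_atlas(list(n_transcripts = 500, n_cell_lines = 66,
                                        n_lineages = 22,
                                        n_planted_specific = 50,
                                        specific_ratio = 0.8, seed = 17))
  prof <- aggregate_by_lineage(sim$atlas)
  planted <- names(sim$truth$specific_transcripts)
  home <- sim$truth$specific_transcripts
  shares <- vapply(planted, function(t) prof$p[t, home[[t]]], numeric(1))
  # pooled home share over all planted transcripts sits at the target ratio
  home_x <- vapply(planted, function(t) prof$x[t, home[[t]]], numeric(1))
  tot_x <- rowSums(prof$x[planted, ])
  expect_equal(sum(home_x) / sum(tot_x), 0.8, tolerance = 0.05)
  expect_gt(mean(shares), 0.7)
  # specificity scores of planted transcripts exceed 1 against the oracle
  oracle <- vapply(planted, function(t)
    entropy_score_oracle(prof$p[t, ], N = 22), numeric(1))
  expect_gt(mean(oracle > 1), 0.95)
  # non-planted transcripts show no systematic lineage preference
  nulls <- setdiff(rownames(prof$p), planted)
  null_top <- apply(prof$p[nulls, ], 1, max)
  expect_lt(mean(null_top), 0.25)
})

test_that("drug simulator has the null and noiseless limits", {
  sim <- simulate_expression_atlas(list(n_transcripts = 60, n_cell_lines = 50,
                                        n_lineages = 10,
                                        n_planted_specific = 0,
                                        dropout_prob = 0.1, seed = 23))
  # dimensions of the planted truth are forced by the config
  d3 <- simulate_drug_response(sim$atlas,
                               list(n_drugs = 3,
                                    n_driver_transcripts_per_drug = 5,
                                    seed = 11))
  expect_equal(dim(d3$auc), c(50, 3))
  expect_equal(nrow(d3$truth), 15)
  d3b <- simulate_drug_response(sim$atlas,
                                list(n_drugs = 3,
                                     n_driver_transcripts_per_drug = 5,
                                     seed = 11))
  expect_identical(d3$auc, d3b$auc)

  # effect 0: AUC independent of expression in expectation
  d0 <- simulate_drug_response(sim$atlas, list(n_drugs = 1, effect_size = 0,
                                               noise_sd = 1, seed = 5))
  rhos <- apply(sim$atlas$values, 1, function(x)
    suppressWarnings(stats::cor(x, d0$auc[, 1], method = "spearman")))
  expect_lt(mean(abs(rhos), na.rm = TRUE), 0.15)

  # noiseless single positive driver: AUC strictly monotone in it
  dm <- simulate_drug_response(sim$atlas,
                               list(n_drugs = 1,
                                    n_driver_transcripts_per_drug = 1,
                                    effect_size = 1, noise_sd = 0, seed = 2))
  drv <- dm$truth$transcript_id[1]
  rho <- stats::cor(sim$atlas$values[drv, ], dm$auc[, 1], method = "spearman")
  expect_equal(abs(rho), 1)
  expect_equal(sign(rho), dm$truth$sign[1])

  # driver pool must survive the prevalence filter
  tiny <- expression_atlas(
    matrix(0, 3, 6, dimnames = list(paste0("t", 1:3), paste0("c", 1:6))),
    setNames(rep("l1", 6), paste0("c", 1:6)))
  expect_error(simulate_drug_response(tiny, list(seed = 1)), "pool")
})

test_that("regulome simulator plants recoverable or unrecoverable edges by design", {
  models <- toy_models(sprintf("T%03d", 1:60))
  full <- simulate_regulome(names(models),
                            list(n_rbps = 3, n_regulated_per_rbp = 10,
                                 frac_bound_of_regulated = 1, seed = 3),
                            models)
  edges <- build_network(full$de_set, full$peak_set, models)
  expect_setequal(edge_key(edges), edge_key(full$truth))

  none <- simulate_regulome(names(models),
                            list(n_rbps = 3, n_regulated_per_rbp = 10,
                                 frac_bound_of_regulated = 0,
                                 n_random_peaks_per_rbp = 0, seed = 3),
                            models)
  expect_equal(nrow(build_network(none$de_set, none$peak_set, models)), 0)

  # planted fold change below the 1.5x threshold never passes the filter
  weak <- simulate_regulome(names(models),
                            list(n_rbps = 2, n_regulated_per_rbp = 10,
                                 lfc_effect = log2(1.2), seed = 3),
                            models)
  for (rbp in names(weak$de_set))
    expect_equal(nrow(filter_significant(weak$de_set[[rbp]])), 0)

  # seeded determinism of tables and peaks
  again <- simulate_regulome(names(models),
                             list(n_rbps = 3, n_regulated_per_rbp = 10,
                                  frac_bound_of_regulated = 1, seed = 3),
                             models)
  expect_identical(full$de_set, again$de_set)
  expect_identical(full$truth, again$truth)
})

test_that("annotation fixture plants one query per category with boundary peaks", {
  ann <- simulate_annotation()
  expect_setequal(unique(ann$truth$category),
                  c("annotated_match", "contain_Ref", "match_Refjunction",
                    "retain_Refintron", "overlap_Refexon", "within_Refintron",
                    "intergenic"))
  expect_equal(sum(ann$truth$is_readthrough), 1)
  # peaks at 0, 500, and 501 nt of the chosen TSSs are all represented
  ev <- tss_evidence(ann$reference, ann$cage_peaks, ann$chromatin_peaks)
  expect_setequal(unique(ev$label),
                  c("both", "cage_only", "chromatin_only", "none"))
})
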