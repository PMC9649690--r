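test_that("expression IO round-trips and rejects malformed input", {
  atlas <- tiny_atlas()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  lin <- withr::local_tempfile(fileext = ".tsv")
  write_expression(atlas, tsv, lin)
  back <- load_expression(tsv, lin)
  expect_equal(back$values, atlas$values)
  expect_equal(back$lineage_of, atlas$lineage_of)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_expression(atlas, mtx, format = "mtx")
  back2 <- load_expression(mtx, lin, format = "mtx")
  expect_equal(back2$values, atlas$values)

  bad <- atlas$values; bad[1, 1] <- -1
  expect_error(expression_atlas(bad, atlas$lineage_of), "non-negative")
  expect_error(expression_atlas(atlas$values, c(c1 = "lung")),
               "without a lineage label")
  dup <- rbind(atlas$values, atlas$values[1, , drop = FALSE])
  expect_error(expression_atlas(dup, atlas$lineage_of), "duplicate")
})

test_that("prevalence filter honors both comparison dialects at the boundary", {
  atlas <- tiny_atlas()
  # tB peaks at 3; tA and tC reach exactly 0.1 in one cell line
  kept <- prevalence_filter(atlas, 0.1, min_count = 1, mode = "inclusive")
  expect_setequal(rownames(kept$values), c("tA", "tB", "tC"))

  # exactly 0.1 everywhere fails the strict drug-mode comparison
  m <- matrix(0.1, 2, 5, dimnames = list(c("x", "y"), paste0("c", 1:5)))
  m[2, ] <- 1
  a <- expression_atlas(m, setNames(rep("l1", 5), paste0("c", 1:5)))
  strict <- prevalence_filter(a, 0.1, min_fraction = 0.2, mode = "strict")
  expect_equal(rownames(strict$values), "y")

  # min_tpm = 0 inclusive is the identity filter
  ident <- prevalence_filter(atlas, 0, min_count = 1, mode = "inclusive")
  expect_equal(ident$values, atlas$values)
  # the input atlas is untouched
  expect_equal(nrow(atlas$values), 3)
})

test_that("lineage aggregation computes x and expression ratios", {
  # one cell line per lineage: x equals the raw column
  m <- matrix(c(8, 1, 1, 0), 1, 4,
              dimnames = list("t", paste0("c", 1:4)))
  a <- expression_atlas(m, setNames(paste0("lin", 1:4), paste0("c", 1:4)))
  prof <- aggregate_by_lineage(a)
  expect_equal(unname(prof$x["t", ]), c(8, 1, 1, 0))
  expect_equal(unname(prof$p["t", ]), c(0.8, 0.1, 0.1, 0))
  expect_equal(prof$N, 4)

  # mean over a lineage's cell lines, and method variants
  atlas <- tiny_atlas()
  pm <- aggregate_by_lineage(atlas, "mean")
  expect_equal(unname(pm$x["tA", "lung"]), mean(c(5, 0.1)))
  ps <- aggregate_by_lineage(atlas, "sum")
  expect_equal(unname(ps$x["tA", "lung"]), 5.1)
  pmed <- aggregate_by_lineage(atlas, "median")
  expect_equal(unname(pmed$x["tA", "skin"]), 1)

  # all-zero transcript is flagged undefined, ratios NA
  m2 <- rbind(m, z = 0)
  a2 <- expression_atlas(m2, a$lineage_of)
  prof2 <- aggregate_by_lineage(a2)
  expect_true(prof2$undefined["z"])
  expect_true(all(is.na(prof2$p["z", ])))
  # defined rows sum to one
  expect_equal(sum(prof2$p["t", ]), 1)
})

test_that("specificity scores match the direct-summation oracle on random profiles", {
  set.seed(101)
  N <- 22
  n <- 1000
  x <- matrix(stats::rexp(n * N), n, N,
              dimnames = list(sprintf("t%04d", 1:n), sprintf("lin%02d", 1:N)))
  # make a handful of rows sparse to exercise the 0 * log2(0) convention
  x[sample(length(x), length(x) %/% 3)] <- 0
  x[rowSums(x) == 0, 1] <- 1
  a <- expression_atlas(x, setNames(sprintf("L%02d", 1:N), sprintf("lin%02d", 1:N)))
  prof <- aggregate_by_lineage(a)
  sc <- specificity_scores(prof)
  oracle <- apply(prof$p, 1, entropy_score_oracle, N = N)
  expect_lt(max(abs(sc$score - oracle)), 1e-9)
  expect_true(all(sc$score >= -1e-12 & sc$score <= log2(N) + 1e-12))
})

test_that("specificity has the analytic limits and the worked profile value", {
  N <- 4
  uniform <- rep(1 / N, N)
  expect_equal(entropy_score_oracle(uniform), 0)
  single <- c(1, 0, 0, 0)
  expect_equal(entropy_score_oracle(single), log2(N))

  x <- rbind(u = rep(2, 4), s = c(9, 0, 0, 0), w = c(8, 1, 1, 0))
  colnames(x) <- paste0("c", 1:4)
  a <- expression_atlas(x, setNames(paste0("lin", 1:4), paste0("c", 1:4)))
  sc <- specificity_scores(aggregate_by_lineage(a))
  expect_equal(sc$score[sc$transcript_id == "u"], 0)
  expect_equal(sc$score[sc$transcript_id == "s"], 2)
  # worked profile p = (0.8, 0.1, 0.1, 0): oracle-derived value
  expect_equal(sc$score[sc$transcript_id == "w"],
               entropy_score_oracle(c(0.8, 0.1, 0.1, 0)))
  expect_equal(sc$score[sc$transcript_id == "w"], 1.0781, tolerance = 1e-4)
  calls <- call_lineage_specific(sc)
  expect_true(calls$is_specific[calls$transcript_id == "w"])
  expect_equal(calls$called_lineage[calls$transcript_id == "w"], "lin1")
  expect_false(calls$is_specific[calls$transcript_id == "u"])
})

test_that("scores are scale invariant and permutation equivariant", {
  set.seed(77)
  N <- 6
  x <- matrix(stats::rexp(50 * N), 50, N,
              dimnames = list(sprintf("t%02d", 1:50), sprintf("lin%d", 1:N)))
  lin <- setNames(sprintf("L%d", 1:N), sprintf("lin%d", 1:N))
  a <- expression_atlas(x, lin)
  sc <- call_lineage_specific(specificity_scores(aggregate_by_lineage(a)))

  a2 <- expression_atlas(x * 1000, lin)
  sc2 <- call_lineage_specific(specificity_scores(aggregate_by_lineage(a2)))
  expect_equal(sc2$score, sc$score)
  expect_equal(sc2$is_specific, sc$is_specific)
  expect_equal(sc2$top_ratio, sc$top_ratio)

  perm <- sample(N)
  xp <- x[, perm]
  ap <- expression_atlas(xp, lin[colnames(xp)])
  scp <- specificity_scores(aggregate_by_lineage(ap))
  expect_equal(scp$score, sc$score)
  expect_equal(scp$top_ratio, sc$top_ratio)
})

test_that("the lineage-specific call applies strict boundaries", {
  mk <- function(p) {
    x <- matrix(p * 100, 1, length(p),
                dimnames = list("t", paste0("c", seq_along(p))))
    a <- expression_atlas(x, setNames(paste0("lin", seq_along(p)),
                                      paste0("c", seq_along(p))))
    call_lineage_specific(specificity_scores(aggregate_by_lineage(a)))
  }
  # top exactly 2x second: not specific (strict >)
  expect_false(mk(c(0.5, 0.25, 0.25 / 3, 0.25 / 3, 0.25 / 3))$is_specific)
  # score exactly 1 is rejected: with N = 2, p = (1, 0) gives score exactly 1
  expect_false(mk(c(1, 0))$is_specific)
  # second ratio 0 with positive top satisfies the 2x condition
  r <- mk(c(1, 0, 0, 0))
  expect_true(r$is_specific)
  # disabling the ratio rule admits score-only calls: concentrated profile
  # over 22 lineages whose top ratio is below 2x the second
  p22 <- c(0.5, 0.3, 0.1, 0.1, rep(0, 18))
  r22 <- mk(p22)
  expect_gt(r22$score, 1)
  expect_false(r22$is_specific)                      # 0.5 < 2 * 0.3
  sc22 <- r22[, c("transcript_id", "score", "top_lineage", "top_ratio",
                  "second_ratio", "undefined")]
  expect_true(call_lineage_specific(sc22, ratio_rule = FALSE)$is_specific)
})
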