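make_drug_atlas <- function(n_tx = 20, n_cl = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_tx * n_cl), n_tx, n_cl,
              dimnames = list(sprintf("tx%02d", 1:n_tx),
                              sprintf("cl%02d", 1:n_cl)))
  expression_atlas(m, setNames(rep("l1", n_cl), colnames(m)))
}

test_that("spearman prefilter matches the rank-formula oracle and handles degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # hand rank formula: d = rank(x) - rank(y), rho = 1 - 6*sum(d^2)/(n(n^2-1))
  d <- rank(x) - rank(y)
  rho_oracle <- 1 - 6 * sum(d^2) / (5 * 24)
  expect_equal(rho_oracle, 0.8)

  m <- rbind(tx1 = x, tx2 = rep(2, 5))
  colnames(m) <- paste0("c", 1:5)
  atlas <- expression_atlas(m, setNames(rep("l1", 5), colnames(m)))
  auc <- matrix(y, 5, 1, dimnames = list(colnames(m), "drugA"))
  pf <- spearman_prefilter(atlas, auc)
  expect_equal(pf$rho[pf$transcript_id == "tx1"], rho_oracle)
  # constant transcript: undefined rho, skipped from calling
  expect_true(is.na(pf$rho[pf$transcript_id == "tx2"]))
  expect_false(pf$pass[pf$transcript_id == "tx2"])

  # monotone noiseless pair: rho = 1 and passes
  atlas2 <- make_drug_atlas(seed = 2)
  auc2 <- matrix(atlas2$values["tx01", ]^2, ncol = 1,
                 dimnames = list(colnames(atlas2$values), "drugB"))
  pf2 <- spearman_prefilter(atlas2, auc2)
  expect_equal(pf2$rho[pf2$transcript_id == "tx01"], 1)
  expect_true(pf2$pass[pf2$transcript_id == "tx01"])

  # missing AUC entries: complete-case n recorded per pair
  auc3 <- auc2
  auc3[1:5, 1] <- NA
  pf3 <- spearman_prefilter(atlas2, auc3)
  expect_true(all(pf3$n == ncol(atlas2$values) - 5))
})

test_that("prediction matrix is standardized and drops constant columns", {
  atlas <- make_drug_atlas(seed = 3)
  X <- build_prediction_matrix(atlas, c("tx01", "tx02", "tx03"))
  expect_lt(max(abs(colMeans(X))), 1e-9)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-9)
  # idempotent within tolerance
  X2 <- scale(X)
  expect_lt(max(abs(X2 - X)), 1e-9)
  # constant column dropped with a warning
  vals <- atlas$values
  vals["tx04", ] <- 7
  a2 <- expression_atlas(vals, atlas$lineage_of)
  expect_warning(X3 <- build_prediction_matrix(a2, c("tx01", "tx04")),
                 "zero-variance")
  expect_equal(colnames(X3), "tx01")
})

test_that("elastic-net tuning is seeded, recovers noiseless signal, and warns on tiny n", {
  set.seed(4)
  n <- 60
  X <- scale(matrix(stats::rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("tx", 1:8))))
  y <- 3 * X[, 1]
  t1 <- tune_elastic_net(X, y, seed = 9)
  t2 <- tune_elastic_net(X, y, seed = 9)
  expect_identical(t1$alpha, t2$alpha)
  expect_identical(t1$lambda, t2$lambda)
  # noiseless linear signal: CV RMSE well under sd(y)
  expect_lt(t1$cv_rmse, 0.1 * sd(y))
  # pure noise: selected model cannot beat sd(y) by much
  yn <- stats::rnorm(n)
  tn <- tune_elastic_net(X, yn, seed = 9)
  expect_lt(abs(tn$cv_rmse - sd(yn)), 0.35 * sd(yn))
  # small n reduces folds with a warning rather than failing
  expect_warning(tune_elastic_net(X[1:12, ], y[1:12], seed = 9), "folds")
})

test_that("predictive score follows the sign-frequency definition", {
  expect_equal(predictive_score(1000, 0, 1000)$score, 1.0)
  expect_equal(predictive_score(1000, 0, 1000)$direction, "positive")
  expect_equal(predictive_score(850, 50, 1000)$score, 0.8)
  expect_equal(predictive_score(0, 850, 1000)$direction, "negative")
  tie <- predictive_score(400, 400, 1000)
  expect_equal(tie$score, 0)
  expect_equal(tie$direction, "none")
  # symmetry in the two frequencies
  expect_equal(predictive_score(850, 50, 1000)$score,
               predictive_score(50, 850, 1000)$score)
  # vectorized bounds
  sc <- predictive_score(c(0, 500, 123), c(0, 500, 456), 1000)$score
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predictive_score(900, 200, 1000))
})

test_that("negating the response flips directions and preserves scores exactly", {
  set.seed(6)
  n <- 50
  X <- scale(matrix(stats::rnorm(n * 10), n, 10,
                    dimnames = list(NULL, paste0("tx", 1:10))))
  y <- as.numeric(X[, 1] - X[, 2]) + stats::rnorm(n, 0, 0.5)
  bs_pos <- bootstrap_predictive_scores(X, y, alpha = 0.5, lambda = 0.05,
                                        B = 200, seed = 13)
  bs_neg <- bootstrap_predictive_scores(X, -y, alpha = 0.5, lambda = 0.05,
                                        B = 200, seed = 13)
  expect_identical(bs_pos$scores$f_pos, bs_neg$scores$f_neg)
  expect_identical(bs_pos$scores$f_neg, bs_neg$scores$f_pos)
  expect_identical(bs_pos$scores$score, bs_neg$scores$score)
  flipped <- c(positive = "negative", negative = "positive", none = "none")
  expect_identical(unname(flipped[bs_pos$scores$direction]),
                   bs_neg$scores$direction)
})

test_that("association calls use an inclusive threshold", {
  sc <- data.frame(transcript_id = c("a", "b", "c"),
                   drug_id = "d1",
                   score = c(0.70, 0.699, 0.9),
                   direction = c("positive", "negative", "positive"))
  called <- call_associations(sc)
  expect_setequal(called$transcript_id, c("a", "c"))
  expect_equal(nrow(call_associations(sc, threshold = 1.01)), 0)
  expect_equal(nrow(call_associations(sc[0, ])), 0)
  # monotone thresholding never adds calls
  expect_true(all(call_associations(sc, 0.9)$transcript_id %in%
                  call_associations(sc, 0.7)$transcript_id))
})

test_that("a single prefiltered transcript still gets a bootstrap score", {
  set.seed(8)
  atlas <- make_drug_atlas(n_tx = 5, n_cl = 40, seed = 8)
  y <- rank(atlas$values["tx01", ]) + stats::rnorm(40, 0, 2)
  auc <- matrix(y, 40, 1, dimnames = list(colnames(atlas$values), "drugS"))
  da <- associate_drugs(atlas, auc, B = 50, seed = 3, n_candidates = 5)
  expect_true("tx01" %in% da$scores$transcript_id)
  expect_equal(da$scores$direction[da$scores$transcript_id == "tx01"],
               "positive")
})
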