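#' Spearman prefilter of transcript-drug pairs
#'
#' Computes the Spearman correlation between every transcript's expression
#' and every drug's AUC over the cell lines with complete observations,
#' adjusts p-values by Benjamini-Hochberg, and flags pairs passing the
#' correlation and FDR thresholds. The correlation test is two-sided by
#' default (`|rho| > rho_min`), so transcripts whose expression tracks
#' either sensitivity or resistance are retained; `two_sided = FALSE`
#' restricts to positive correlations.
#'
#' @param atlas an [expression_atlas()] object (already prevalence-filtered
#'   in the strict drug-mode dialect — see [prevalence_filter()]).
#' @param auc numeric matrix of drug response AUC, rows = cell lines,
#'   columns = drugs; `NA` entries allowed and handled per pair by
#'   complete-case restriction.
#' @param rho_min correlation threshold (default 0.2, strict `>`).
#' @param fdr_max BH-FDR threshold (default 0.05, strict `<`).
#' @param two_sided use `|rho|` (default) rather than signed rho.
#' @param fdr_scope `"global"` adjusts across all evaluated pairs (default);
#'   `"per_drug"` adjusts within each drug.
#' @return data.frame with one row per evaluated pair: `transcript_id`,
#'   `drug_id`, `n`, `rho`, `pvalue`, `fdr`, `pass`. Pairs with fewer than
#'   3 complete observations or zero variance are reported with `NA` rho
#'   and `pass = FALSE`.
#' @export
spearman_prefilter <- function(atlas, auc, rho_min = 0.2, fdr_max = 0.05,
                               two_sided = TRUE,
                               fdr_scope = c("global", "per_drug")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(atlas, "ExpressionAtlas"), is.matrix(auc))
  shared <- intersect(colnames(atlas$values), rownames(auc))
  if (length(shared) < 3)
    stop("fewer than 3 shared cell lines between atlas and drug matrix",
         call. = FALSE)
  expr <- atlas$values[, shared, drop = FALSE]
  auc <- auc[shared, , drop = FALSE]
  res <- list()
  for (drug in colnames(auc)) {
    y <- auc[, drug]
    ok <- !is.na(y)
    for (tx in rownames(expr)) {
      x <- expr[tx, ok]
      yy <- y[ok]
      if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(yy) == 0) {
        res[[length(res) + 1L]] <- data.frame(
          transcript_id = tx, drug_id = drug, n = sum(ok),
          rho = NA_real_, pvalue = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x, yy, method = "spearman", exact = FALSE))
      res[[length(res) + 1L]] <- data.frame(
        transcript_id = tx, drug_id = drug, n = sum(ok),
        rho = unname(ct$estimate), pvalue = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  res$fdr <- NA_real_
  defined <- !is.na(res$pvalue)
  if (fdr_scope == "global") {
    res$fdr[defined] <- stats::p.adjust(res$pvalue[defined], method = "BH")
  } else {
    for (drug in unique(res$drug_id)) {
      idx <- defined & res$drug_id == drug
      res$fdr[idx] <- stats::p.adjust(res$pvalue[idx], method = "BH")
    }
  }
  stat <- if (two_sided) abs(res$rho) else res$rho
  res$pass <- !is.na(res$rho) & stat > rho_min & res$fdr < fdr_max
  rownames(res) <- NULL
  res
}

#' Build a standardized prediction matrix for one drug
#'
#' Assembles the cell-line-by-transcript expression matrix for the
#' transcripts passing the prefilter for a drug, restricted to cell lines
#' with an observed AUC, and normalizes each transcript column to zero mean
#' and unit standard deviation. Zero-variance columns are dropped with a
#' warning.
#'
#' @param atlas an [expression_atlas()] object.
#' @param transcripts character vector of transcript ids (columns).
#' @param cell_lines character vector of cell lines (rows); defaults to all
#'   atlas cell lines.
#' @return Standardized numeric matrix, cell lines x transcripts.
#' @export
build_prediction_matrix <- function(atlas, transcripts,
                                    cell_lines = colnames(atlas$values)) {
  stopifnot(length(transcripts) >= 1)
  X <- t(atlas$values[transcripts, cell_lines, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance transcript column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  scale(X)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# glmnet requires >= 2 predictor columns; pad single-column matrices with an
# all-zero dummy whose coefficient is identically zero, and drop it again
fit_enet <- function(X, y, alpha, lambda) {
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `.pad` = 0)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                        standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[setdiff(names(beta), ".pad")]
  list(fit = fit, beta = beta, padded = padded)
}

predict_enet <- function(fitted, X) {
  if (fitted$padded) X <- cbind(X, `.pad` = 0)
  as.numeric(stats::predict(fitted$fit, X))
}

lambda_max_for <- function(X, y, alpha) {
  # smallest lambda zeroing all coefficients under the pathwise convention
  n <- nrow(X)
  max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha, 1e-3))
}

#' Tune elastic-net hyperparameters by repeated cross-validation
#'
#' Draws `n_candidates` random (alpha, lambda) pairs — alpha uniform on
#' [0.05, 1], lambda log-uniform between the pathwise lambda_max for the
#' drawn alpha and lambda_max/1000 — and evaluates each by `n_repeats`
#' rounds of `n_folds`-fold cross-validated root-mean-squared error,
#' returning the candidate with the smallest mean RMSE. Ties are broken
#' toward the larger lambda (the sparser model). Fold assignment and the
#' candidate draw are deterministic functions of `seed`.
#'
#' @param X standardized predictor matrix (cell lines x transcripts).
#' @param y numeric response (drug AUC).
#' @param n_folds folds per round (default 10; reduced with a warning when
#'   `n` is too small for 2 observations per fold).
#' @param n_repeats cross-validation rounds (default 5).
#' @param n_candidates random-search candidates (default 25).
#' @param seed integer seed.
#' @return List: `alpha`, `lambda`, `cv_rmse` (mean RMSE of the winner),
#'   `candidates` (data.frame of all evaluated candidates).
#' @export
tune_elastic_net <- function(X, y, n_folds = 10, n_repeats = 5,
                             n_candidates = 25, seed = 1) {
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  if (n < 2 * n_folds) {
    n_folds <- max(2L, n %/% 2L)
    warning("n too small for requested folds; using ", n_folds, " folds",
            call. = FALSE)
  }
  rng <- local_rng(seed)
  alphas <- rng(stats::runif(n_candidates, 0.05, 1))
  lmaxes <- vapply(alphas, function(a) lambda_max_for(X, y, a), numeric(1))
  lambdas <- rng(exp(log(lmaxes) - stats::runif(n_candidates, 0, log(1e3))))
  folds <- lapply(seq_len(n_repeats), function(r)
    rng(sample(rep_len(seq_len(n_folds), n))))
  cv_rmse <- vapply(seq_len(n_candidates), function(k) {
    errs <- numeric(0)
    for (r in seq_len(n_repeats)) {
      f <- folds[[r]]
      for (fold in seq_len(n_folds)) {
        test <- f == fold
        fit <- fit_enet(X[!test, , drop = FALSE], y[!test],
                        alphas[k], lambdas[k])
        pred <- predict_enet(fit, X[test, , drop = FALSE])
        errs <- c(errs, rmse(y[test], pred))
      }
    }
    mean(errs)
  }, numeric(1))
  best <- order(cv_rmse, -lambdas)[1]
  list(alpha = alphas[best], lambda = lambdas[best], cv_rmse = cv_rmse[best],
       candidates = data.frame(alpha = alphas, lambda = lambdas,
                               cv_rmse = cv_rmse))
}

# evaluate expr under a private RNG stream seeded once, without touching
# the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
}

#' Bootstrap sign-frequency predictive scores
#'
#' Resamples cell lines with replacement `B` times, refits the elastic net
#' at the fixed tuned (alpha, lambda) on each resample, and records the
#' sign of every transcript's coefficient. The predictive score of a
#' transcript is the absolute difference between its positive- and
#' negative-coefficient frequencies divided by `B`:
#' score = (F\[beta>0\] - F\[beta<0\])/B when positives dominate, the
#' mirror image when negatives dominate, and 0 on a tie. Exact zeros count
#' in neither frequency. Resamples with zero response variance are redrawn
#' (and counted in `n_redrawn`).
#'
#' @param X standardized predictor matrix (cell lines x transcripts).
#' @param y numeric response.
#' @param alpha,lambda tuned elastic-net parameters.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; resample indices are a deterministic function
#'   of it, so re-running with a transformed `y` reuses identical resamples.
#' @return List with `scores` (data.frame: `transcript_id`, `f_pos`,
#'   `f_neg`, `B`, `score`, `direction`) and `n_redrawn`.
#' @export
bootstrap_predictive_scores <- function(X, y, alpha, lambda, B = 1000,
                                        seed = 1) {
  stopifnot(nrow(X) == length(y), B >= 1)
  n <- nrow(X)
  rng <- local_rng(seed)
  f_pos <- f_neg <- stats::setNames(integer(ncol(X)), colnames(X))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- rng(sample.int(n, n, replace = TRUE))
      if (stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    beta <- fit_enet(X[idx, , drop = FALSE], y[idx], alpha, lambda)$beta
    f_pos <- f_pos + (beta > 0)
    f_neg <- f_neg + (beta < 0)
  }
  sc <- predictive_score(f_pos, f_neg, B)
  list(scores = data.frame(transcript_id = colnames(X),
                           f_pos = as.integer(f_pos),
                           f_neg = as.integer(f_neg),
                           B = B,
                           score = sc$score,
                           direction = sc$direction,
                           row.names = NULL, stringsAsFactors = FALSE),
       n_redrawn = n_redrawn)
}

#' Predictive score from bootstrap sign frequencies
#'
#' @param f_pos,f_neg counts of resamples with positive / negative
#'   coefficients (vectorized).
#' @param B number of resamples.
#' @return List of vectors `score` (in \[0, 1\]) and `direction`
#'   (`positive`/`negative`/`none`).
#' @export
predictive_score <- function(f_pos, f_neg, B) {
  stopifnot(all(f_pos + f_neg <= B), all(f_pos >= 0), all(f_neg >= 0))
  score <- abs(f_pos - f_neg) / B
  direction <- ifelse(f_pos > f_neg, "positive",
               ifelse(f_neg > f_pos, "negative", "none"))
  score[direction == "none"] <- 0
  list(score = score, direction = direction)
}

#' Call transcript-drug associations from predictive scores
#'
#' @param scores data.frame of bootstrap scores (from
#'   [bootstrap_predictive_scores()]`$scores`, possibly with `drug_id` and
#'   `rho` columns attached).
#' @param threshold minimum predictive score, inclusive (default 0.7).
#' @return The subset with `score >= threshold`.
#' @export
call_associations <- function(scores, threshold = 0.7) {
  scores[scores$score >= threshold, , drop = FALSE]
}

#' Full transcript-drug association analysis
#'
#' Runs the prefilter, per-drug prediction-matrix construction, elastic-net
#' tuning, and bootstrap scoring, and returns the called associations.
#'
#' @param atlas prevalence-filtered [expression_atlas()].
#' @param auc AUC matrix, cell lines x drugs.
#' @param rho_min,fdr_max prefilter thresholds.
#' @param B bootstrap resamples.
#' @param score_threshold association call threshold (inclusive).
#' @param seed integer seed.
#' @param n_folds,n_repeats,n_candidates tuning controls (see
#'   [tune_elastic_net()]).
#' @return List: `prefilter` (all evaluated pairs), `scores` (bootstrap
#'   scores for every prefiltered pair), `associations` (called pairs),
#'   `tuning` (per-drug alpha/lambda).
#' @export
associate_drugs <- function(atlas, auc, rho_min = 0.2, fdr_max = 0.05,
                            B = 1000, score_threshold = 0.7, seed = 1,
                            n_folds = 10, n_repeats = 5, n_candidates = 25) {
  pref <- spearman_prefilter(atlas, auc, rho_min, fdr_max)
  shared <- intersect(colnames(atlas$values), rownames(auc))
  all_scores <- list()
  tuning <- list()
  for (drug in colnames(auc)) {
    pass_tx <- pref$transcript_id[pref$drug_id == drug & pref$pass]
    if (!length(pass_tx)) next
    ok <- shared[!is.na(auc[shared, drug])]
    X <- suppressWarnings(build_prediction_matrix(atlas, pass_tx, ok))
    if (!ncol(X)) next
    y <- auc[ok, drug]
    tuned <- tune_elastic_net(X, y, n_folds, n_repeats, n_candidates,
                              seed = derive_seed(seed, drug, "tune"))
    bs <- bootstrap_predictive_scores(X, y, tuned$alpha, tuned$lambda, B,
                                      seed = derive_seed(seed, drug, "boot"))
    sc <- bs$scores
    sc$drug_id <- drug
    sc$rho <- pref$rho[match(paste(sc$transcript_id, drug),
                             paste(pref$transcript_id, pref$drug_id))]
    all_scores[[drug]] <- sc
    tuning[[drug]] <- data.frame(drug_id = drug, alpha = tuned$alpha,
                                 lambda = tuned$lambda,
                                 cv_rmse = tuned$cv_rmse,
                                 stringsAsFactors = FALSE)
  }
  scores <- if (length(all_scores)) do.call(rbind, all_scores) else
    data.frame(transcript_id = character(0), f_pos = integer(0),
               f_neg = integer(0), B = integer(0), score = numeric(0),
               direction = character(0), drug_id = character(0),
               rho = numeric(0), stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  assoc <- call_associations(scores, score_threshold)
  rownames(assoc) <- NULL
  list(prefilter = pref, scores = scores, associations = assoc,
       tuning = if (length(tuning)) do.call(rbind, c(tuning, make.row.names = FALSE))
                else data.frame())
}

# stable small-integer seed derived from a base seed and string tags
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147480009
  as.integer(h)
}
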