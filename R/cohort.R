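# Cohort-level analysis: the 2-D PCA disease space, indexing of new or
# sequential samples, random-forest subtype classification with
# cross-validated AUC and Gini importances, feature integration with
# external per-sample vectors, and rank-based group comparisons.

#' Assemble a cohort feature matrix
#'
#' @param X Numeric matrix or data frame, samples x features.
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Class label per sample.
#' @return A list of class `cohort_matrix`.
#' @export
cohort_matrix <- function(X, sample_ids, labels) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop_invalid("feature names not unique")
  if (anyDuplicated(sample_ids)) stop_invalid("sample ids not unique")
  if (length(sample_ids) != nrow(X) || length(labels) != nrow(X)) {
    stop_invalid("sample_ids / labels length must match rows of X")
  }
  if (anyNA(X)) stop_invalid("missing values in feature matrix")
  rownames(X) <- sample_ids
  structure(list(sample_ids = sample_ids, labels = labels, X = X,
                 feature_names = colnames(X)),
            class = "cohort_matrix")
}

#' Fit the 2-D PCA disease space
#'
#' Features are z-scored with the cohort mean and standard deviation
#' (frozen at fit, so later indexing is stable); the top two principal
#' components are retained with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param cohort A [cohort_matrix()]; needs at least 3 samples and 2
#'   usable (non-constant) features.
#' @return A list of class `disease_space`: orthonormal `loadings`
#'   (features x 2), `explained_variance`, frozen `center`/`scale`,
#'   training `scores` and `sample_ids`.
#' @export
fit_disease_space <- function(cohort) {
  X <- cohort$X
  if (nrow(X) < 3) stop_invalid("need at least 3 samples")
  sds <- apply(X, 2, stats::sd)
  drop_feats <- names(sds)[sds < 1e-12]
  if (length(drop_feats) > 0) {
    warning("dropping zero-variance features: ",
            paste(drop_feats, collapse = ", "))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(X) < 2) stop_invalid("fewer than 2 usable features")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  L <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  scores <- Z %*% L
  structure(list(loadings = L,
                 explained_variance = pc$sdev[1:2]^2,
                 center = ctr, scale = scl,
                 feature_names = colnames(X),
                 scores = scores, sample_ids = cohort$sample_ids),
            class = "disease_space")
}

#' Project a feature vector into a fitted disease space
#'
#' The space is frozen: new samples never alter the loadings or the
#' standardisation reference.
#'
#' @param space A `disease_space`.
#' @param fv Named numeric vector (or single-row matrix) containing the
#'   space's features.
#' @return Numeric length-2 coordinates `c(PC1, PC2)`.
#' @export
index_sample <- function(space, fv) {
  if (is.matrix(fv)) fv <- fv[1, ]
  missing_f <- setdiff(space$feature_names, names(fv))
  if (length(missing_f) > 0) {
    stop("missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  z <- (fv[space$feature_names] - space$center) / space$scale
  drop(z %*% space$loadings)
}

# Seeded stratified fold assignment; every class is spread across folds.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  fold
}

#' Random-forest subtype classification with cross-validated AUC
#'
#' Stratified k-fold cross-validation of a random forest; out-of-fold
#' class probabilities are pooled into one AUC (per-fold AUCs are also
#' reported) and Gini importances come from a forest refit on all data.
#'
#' @param cohort A [cohort_matrix()] with exactly the samples to use.
#' @param positive_label The class treated as positive.
#' @param n_trees Trees per forest (default 100).
#' @param folds Cross-validation folds (default 3).
#' @param seed Seed for folds and forests.
#' @param space Optional `disease_space`; when supplied the classifier
#'   consumes the 2-D PCA coordinates instead of the raw features.
#' @return A list of class `classifier_report`: `auc` (pooled
#'   out-of-fold), `fold_aucs`, `gini_importances` (normalised to sum 1),
#'   `oof_scores`, `n_trees`, `folds`, `seed`.
#' @export
classify <- function(cohort, positive_label, n_trees = 100L, folds = 3L,
                     seed = 1L, space = NULL) {
  y <- factor(cohort$labels == positive_label, levels = c(FALSE, TRUE),
              labels = c("neg", "pos"))
  counts <- table(y)
  if (any(counts < folds)) {
    stop_invalid("each class needs at least as many samples as folds")
  }
  X <- if (is.null(space)) cohort$X else {
    t(apply(cohort$X, 1, function(r) index_sample(space,
                                                  r[cohort$feature_names])))
  }
  colnames(X) <- make.names(colnames(X))
  fold <- stratified_folds(as.character(y), folds, seed)
  oof <- numeric(nrow(X))
  fold_aucs <- numeric(folds)
  rf_seeds <- derive_seeds(seed + 1L, folds + 1L)
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- fold == k
    rf <- with_seed(rf_seeds[k],
                    randomForest::randomForest(X[tr, , drop = FALSE],
                                               y[tr], ntree = n_trees))
    oof[te] <- stats::predict(rf, X[te, , drop = FALSE],
                              type = "prob")[, "pos"]
    fold_aucs[k] <- as.numeric(pROC::auc(
      pROC::roc(response = y[te], predictor = oof[te],
                levels = c("neg", "pos"), direction = "<", quiet = TRUE)))
  }
  auc <- as.numeric(pROC::auc(
    pROC::roc(response = y, predictor = oof,
              levels = c("neg", "pos"), direction = "<", quiet = TRUE)))
  rf_full <- with_seed(rf_seeds[folds + 1L],
                       randomForest::randomForest(X, y, ntree = n_trees,
                                                  importance = FALSE))
  imp <- randomForest::importance(rf_full, type = 2)[, 1]
  imp <- imp / sum(imp)
  structure(list(auc = auc, fold_aucs = fold_aucs,
                 gini_importances = imp, oof_scores = oof,
                 n_trees = as.integer(n_trees), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "classifier_report")
}

#' Join external per-sample features onto a fibrosis cohort
#'
#' Inner join on `sample_id`; fibrosis features are namespaced `fib.*` and
#' external ones `ext.*`. Samples without external features are dropped
#' with a warning.
#'
#' @param fibrosis A [cohort_matrix()].
#' @param external Data frame with a `sample_id` column and numeric
#'   feature columns (e.g. megakaryocyte features read from CSV).
#' @return A combined [cohort_matrix()].
#' @export
combine_features <- function(fibrosis, external) {
  if (!"sample_id" %in% names(external)) {
    stop_invalid("external table needs a sample_id column")
  }
  common <- intersect(fibrosis$sample_ids, external$sample_id)
  if (length(common) == 0) stop_invalid("no overlapping sample ids")
  if (length(common) < 3) {
    stop_invalid("need at least 3 overlapping samples, got ",
                 length(common))
  }
  dropped <- setdiff(fibrosis$sample_ids, common)
  if (length(dropped) > 0) {
    warning(length(dropped),
            " sample(s) without external features dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  keep <- match(common, fibrosis$sample_ids)
  ext <- external[match(common, external$sample_id),
                  setdiff(names(external), "sample_id"), drop = FALSE]
  Xf <- fibrosis$X[keep, , drop = FALSE]
  colnames(Xf) <- paste0("fib.", colnames(Xf))
  Xe <- as.matrix(ext)
  colnames(Xe) <- paste0("ext.", colnames(Xe))
  cohort_matrix(cbind(Xf, Xe), common, fibrosis$labels[keep])
}

# Distribution-free order-statistic confidence interval for the median at
# >= 95% coverage (binomial argument). Returns the sample range when n is
# too small for 95% coverage.
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  alpha <- 1 - conf
  k <- stats::qbinom(alpha / 2, n, 0.5)
  while (k > 0 && stats::pbinom(k - 1, n, 0.5) > alpha / 2) k <- k - 1
  if (k < 1) return(c(lower = x[1], upper = x[n]))
  c(lower = x[k], upper = x[n + 1 - k])
}

#' Rank-based comparison of one feature between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test: exact when both groups have at
#' most 20 samples and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. The p value is
#' Bonferroni-adjusted by the declared number of comparisons, and each
#' group median gets a distribution-free 95% confidence interval.
#'
#' @param values Numeric feature values, one per sample.
#' @param groups Group label per sample.
#' @param group_a,group_b The two labels to compare.
#' @param n_comparisons Bonferroni family size (explicit, never inferred).
#' @return A list of class `group_comparison`: `statistic` (rank-sum U),
#'   `p_raw`, `p_adjusted`, `median_ci_a`, `median_ci_b`, group sizes.
#' @export
compare_groups <- function(values, groups, group_a, group_b,
                           n_comparisons = 1L) {
  xa <- values[groups == group_a]
  xb <- values[groups == group_b]
  if (length(xa) < 2 || length(xb) < 2) {
    stop("empty group error: each group needs at least 2 samples",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(xa, xb)) > 0
  use_exact <- length(xa) <= 20 && length(xb) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = use_exact,
                                            correct = TRUE))
  p_adj <- min(1, wt$p.value * n_comparisons)
  structure(list(group_a = group_a, group_b = group_b,
                 statistic = unname(wt$statistic),
                 p_raw = wt$p.value, p_adjusted = p_adj,
                 median_ci_a = median_ci(xa), median_ci_b = median_ci(xb),
                 n_a = length(xa), n_b = length(xb),
                 exact = use_exact),
            class = "group_comparison")
}
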