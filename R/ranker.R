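# Pairwise (RankNet-style) ranking scorer. A fixed convolutional feature
# bank summarises each tile (fiber darkness, edge energy, oriented line
# responses); a linear head on those pooled features is trained with the
# pairwise logistic cross-entropy, then min-max calibrated to CIF scores
# in [0, 1].

#' Convolutional feature-bank backbone
#'
#' Defines the fixed convolutional maps pooled per tile: darkness, a
#' dark-pixel indicator and its 3x3 smoothing, Sobel gradient energy,
#' Laplacian magnitude and four oriented line-detector responses, plus the
#' within-tile darkness standard deviation. The trainable part of the model
#' is the linear scoring head on these pooled features.
#'
#' @param dark_threshold Gray level (0-1 scale) below which a pixel counts
#'   as fiber-dark.
#' @return A list of class `cif_backbone`.
#' @export
cif_backbone <- function(dark_threshold = 0.55) {
  line <- function(m) m / sum(abs(m))
  kernels <- list(
    sobel_x = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
    sobel_y = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
    laplace = matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
    line_h = line(matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3, 3,
                         byrow = TRUE)),
    line_v = line(matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3, 3)),
    line_d1 = line(matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3)),
    line_d2 = line(matrix(c(-1, -1, 2, -1, 2, -1, 2, -1, -1), 3, 3)),
    box3 = matrix(1 / 9, 3, 3)
  )
  structure(list(dark_threshold = dark_threshold, kernels = kernels,
                 feature_names = c("darkness", "dark_frac",
                                   "dark_frac_sm", "grad_energy",
                                   "laplace_abs", "line_h", "line_v",
                                   "line_d1", "line_d2", "dark_sd")),
            class = "cif_backbone")
}

# Pixel-level response maps for one grayscale image (0-255).
backbone_maps <- function(backbone, image) {
  g <- image / 255
  d <- 1 - g
  dark <- (g < backbone$dark_threshold) * 1
  k <- backbone$kernels
  relu <- function(x) pmax(x, 0)
  list(darkness = d,
       dark_frac = dark,
       dark_frac_sm = conv2_replicate(dark, k$box3),
       grad_energy = abs(conv2_replicate(g, k$sobel_x)) +
         abs(conv2_replicate(g, k$sobel_y)),
       laplace_abs = abs(conv2_replicate(g, k$laplace)),
       line_h = relu(conv2_replicate(d, k$line_h)),
       line_v = relu(conv2_replicate(d, k$line_v)),
       line_d1 = relu(conv2_replicate(d, k$line_d1)),
       line_d2 = relu(conv2_replicate(d, k$line_d2)),
       darkness_sq = d^2)
}

#' Pooled backbone features for every tile of a grid
#'
#' Convolutional responses are computed once over the whole image and
#' pooled (mean) over each tile footprint via summed-area tables; the last
#' feature is the within-tile standard deviation of darkness.
#'
#' @param image Grayscale matrix (0-255).
#' @param grid A `tile_grid` (all rows are used, included or not).
#' @param backbone A [cif_backbone()].
#' @return Numeric matrix `n_tiles x 10` with `tile_id` rownames.
#' @export
tile_features <- function(image, grid, backbone = cif_backbone()) {
  size <- attr(grid, "size")
  maps <- backbone_maps(backbone, image)
  area <- as.numeric(size)^2
  pool <- function(m) {
    window_sums(integral_image(m), grid$row0, grid$col0, size) / area
  }
  means <- vapply(maps, pool, numeric(nrow(grid)))
  if (nrow(grid) == 1) means <- matrix(means, nrow = 1,
                                       dimnames = list(NULL, names(maps)))
  m1 <- means[, "darkness"]
  m2 <- means[, "darkness_sq"]
  feats <- cbind(means[, setdiff(colnames(means), "darkness_sq"),
                       drop = FALSE],
                 dark_sd = sqrt(pmax(m2 - m1^2, 0)))
  colnames(feats) <- backbone$feature_names
  rownames(feats) <- grid$tile_id
  feats
}

#' Create an untrained ranking model
#'
#' @param backbone A [cif_backbone()].
#' @param seed Run seed recorded in the training metadata.
#' @return A list of class `ranking_model` with the linear head `w`
#'   (zero-initialised; the model is linear in its head, so no symmetry
#'   breaking is needed), frozen feature standardisation, min-max
#'   normalisation anchors (unset until [calibrate_scores()]) and training
#'   metadata.
#' @export
new_ranking_model <- function(backbone = cif_backbone(), seed = 1L) {
  p <- length(backbone$feature_names)
  w <- rep(0, p)
  structure(list(backbone = backbone, w = w,
                 feat_center = rep(0, p), feat_scale = rep(1, p),
                 standardized = FALSE,
                 norm_low = NA_real_, norm_high = NA_real_,
                 training_meta = list(seed = as.integer(seed),
                                      rounds = list())),
            class = "ranking_model")
}

# Raw (uncalibrated) scalar scores for a feature matrix.
raw_scores <- function(model, features) {
  z <- sweep(sweep(features, 2, model$feat_center), 2, model$feat_scale, "/")
  drop(z %*% model$w)
}

#' RankNet pairwise probability
#'
#' Probability that item a outranks item b: the logistic of the score
#' difference, `1 / (1 + exp(-(s_a - s_b)))`. Satisfies
#' `P(a, b) + P(b, a) = 1`.
#'
#' @param s_a,s_b Finite raw scores (vectorised).
#' @return Probabilities in (0, 1).
#' @export
pairwise_probability <- function(s_a, s_b) {
  if (any(!is.finite(s_a)) || any(!is.finite(s_b))) {
    stop_invalid("scores must be finite")
  }
  stats::plogis(s_a - s_b)
}

#' RankNet pairwise cross-entropy loss
#'
#' Mean binary cross-entropy of the pairwise probabilities against the
#' 0/1 comparison labels.
#'
#' @param label 0/1 labels (1 = first item more severe).
#' @param prob Model probabilities from [pairwise_probability()].
#' @return Non-negative scalar loss.
#' @export
pairwise_loss <- function(label, prob) {
  if (length(label) == 0) stop_invalid("empty batch")
  if (length(label) != length(prob)) {
    stop_invalid("label and prob lengths differ")
  }
  eps <- 1e-15
  p <- pmin(1 - eps, pmax(eps, prob))
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

# Pairwise accuracy with ties counted as half correct.
pairwise_accuracy <- function(s_a, s_b, label) {
  pred <- sign(s_a - s_b)
  truth <- ifelse(label == 1, 1, -1)
  mean(ifelse(pred == 0, 0.5, (pred == truth) * 1))
}

#' Train the ranking head for one round
#'
#' Splits the labeled pairs into training and held-out subsets (disjoint
#' within the round), freezes feature standardisation on first use, and
#' runs full-batch gradient descent on the pairwise cross-entropy.
#'
#' @param model A `ranking_model`.
#' @param features Feature matrix with `tile_id` rownames covering every
#'   tile referenced by `pairs`.
#' @param pairs Data frame with `tile_a_id`, `tile_b_id`, `label` (1 if a
#'   is more severe).
#' @param epochs Gradient-descent epochs; 0 leaves the model unchanged.
#' @param lr Learning rate.
#' @param momentum Classical momentum coefficient.
#' @param l2 Ridge penalty on the head weights.
#' @param holdout_frac Fraction of pairs held out for accuracy estimation.
#' @param seed Seed for the split.
#' @return List with the updated `model` and a `round` record (round index,
#'   pair counts, held-out accuracy, loss curve).
#' @export
train_round <- function(model, features, pairs, epochs = 300, lr = 0.5,
                        momentum = 0.9, l2 = 1e-4, holdout_frac = 0.2,
                        seed = 1L) {
  if (nrow(pairs) == 0) stop_invalid("empty pair set")
  ids <- unique(c(pairs$tile_a_id, pairs$tile_b_id))
  if (length(ids) < 2) {
    stop("training-data error: pairs reference fewer than 2 distinct tiles",
         call. = FALSE)
  }
  missing_ids <- setdiff(ids, rownames(features))
  if (length(missing_ids) > 0) {
    stop_invalid("features missing for tiles: ",
                 paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  n <- nrow(pairs)
  n_hold <- round(holdout_frac * n)
  hold <- with_seed(seed, sample.int(n, n_hold))
  train <- if (n_hold > 0) pairs[-hold, , drop = FALSE] else pairs
  heldout <- pairs[hold, , drop = FALSE]

  if (!model$standardized) {
    tr_ids <- unique(c(train$tile_a_id, train$tile_b_id))
    f <- features[tr_ids, , drop = FALSE]
    ctr <- colMeans(f)
    scl <- apply(f, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    model$feat_center <- ctr
    model$feat_scale <- scl
    model$standardized <- TRUE
  }

  za <- sweep(sweep(features[train$tile_a_id, , drop = FALSE], 2,
                    model$feat_center), 2, model$feat_scale, "/")
  zb <- sweep(sweep(features[train$tile_b_id, , drop = FALSE], 2,
                    model$feat_center), 2, model$feat_scale, "/")
  D <- za - zb
  y <- train$label
  w <- model$w
  vel <- numeric(length(w))
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    p <- stats::plogis(drop(D %*% w))
    losses[e] <- pairwise_loss(y, p) + l2 / 2 * sum(w^2)
    grad <- drop(crossprod(D, p - y)) / nrow(D) + l2 * w
    vel <- momentum * vel - lr * grad
    w <- w + vel
  }
  model$w <- w

  acc <- if (nrow(heldout) > 0) {
    sa <- raw_scores(model, features[heldout$tile_a_id, , drop = FALSE])
    sb <- raw_scores(model, features[heldout$tile_b_id, , drop = FALSE])
    pairwise_accuracy(sa, sb, heldout$label)
  } else NA_real_

  round_rec <- list(round_index = length(model$training_meta$rounds) + 1L,
                    n_train = nrow(train), n_heldout = nrow(heldout),
                    heldout_accuracy = acc, loss_curve = losses,
                    heldout_pairs = heldout)
  model$training_meta$rounds <-
    c(model$training_meta$rounds, list(round_rec))
  list(model = model, round = round_rec)
}

#' Propose unlabeled tile pairs for the next annotation round
#'
#' @param model A `ranking_model` (used by the uncertainty strategy).
#' @param features Feature matrix of the candidate tiles.
#' @param n_pairs Number of pairs requested; truncated with a warning when
#'   it exceeds the number of distinct pairs.
#' @param strategy `"uniform"` samples distinct pairs without replacement;
#'   `"uncertainty"` returns the pairs with the smallest absolute score
#'   difference first (nearby ranks only, deterministic).
#' @param seed Seed for uniform sampling.
#' @return Data frame with `tile_a_id`, `tile_b_id`.
#' @export
select_pairs <- function(model, features, n_pairs,
                         strategy = c("uniform", "uncertainty"),
                         seed = 1L) {
  strategy <- match.arg(strategy)
  ids <- rownames(features)
  n <- length(ids)
  if (n < 2) stop_invalid("need at least 2 candidate tiles")
  n_avail <- n * (n - 1) / 2
  if (n_pairs > n_avail) {
    warning("n_pairs exceeds available distinct pairs; truncated to ",
            n_avail)
    n_pairs <- n_avail
  }
  if (strategy == "uniform") {
    sel <- with_seed(seed, sample(n_avail, n_pairs))
    # decode linear index k (1-based) of the upper triangle, row-major
    k <- sel - 1
    i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
    j <- k - i * n + i * (i + 1) / 2 + i + 1
    data.frame(tile_a_id = ids[i + 1], tile_b_id = ids[j + 1])
  } else {
    s <- raw_scores(model, features)
    ord <- order(s, seq_len(n))
    max_off <- min(20L, n - 1L)
    ai <- integer(0); bi <- integer(0); gap <- numeric(0)
    for (off in seq_len(max_off)) {
      idx <- seq_len(n - off)
      ai <- c(ai, ord[idx]); bi <- c(bi, ord[idx + off])
      gap <- c(gap, abs(s[ord[idx + off]] - s[ord[idx]]))
    }
    o <- order(gap, ai, bi)
    take <- utils::head(o, n_pairs)
    data.frame(tile_a_id = ids[ai[take]], tile_b_id = ids[bi[take]])
  }
}

#' Simulate noisy annotators over oracle-labeled pairs
#'
#' Each annotator independently reports the oracle label with probability
#' `concordance`; the training label is the majority vote.
#'
#' @param pairs Data frame with `tile_a_id`, `tile_b_id`.
#' @param oracle 0/1 vector of oracle labels (1 = a more severe), one per
#'   pair.
#' @param concordance Per-annotator probability of agreeing with the
#'   oracle; must lie in (0.5, 1].
#' @param n_annotators Odd number of annotators.
#' @param seed Seed.
#' @return List with `pairs` (label column = majority vote),
#'   `annotator_labels` (matrix), `inter_annotator_agreement` (mean
#'   pairwise agreement across annotator pairs) and `majority_accuracy`
#'   (majority vote vs oracle).
#' @export
simulate_annotators <- function(pairs, oracle, concordance = 0.884,
                                n_annotators = 3L, seed = 1L) {
  if (concordance <= 0.5 || concordance > 1) {
    stop_invalid("concordance must lie in (0.5, 1]")
  }
  if (n_annotators %% 2 != 1) stop_invalid("n_annotators must be odd")
  if (length(oracle) != nrow(pairs)) {
    stop_invalid("oracle labels must match the number of pairs")
  }
  n <- nrow(pairs)
  lab <- with_seed(seed, {
    agree <- matrix(stats::runif(n * n_annotators) < concordance,
                    n, n_annotators)
    ifelse(agree, oracle, 1 - oracle)
  })
  majority <- as.integer(rowSums(lab) > n_annotators / 2)
  combs <- utils::combn(n_annotators, 2)
  agr <- mean(apply(combs, 2, function(ij) mean(lab[, ij[1]] == lab[, ij[2]])))
  pairs$label <- majority
  list(pairs = pairs, annotator_labels = lab,
       inter_annotator_agreement = agr,
       majority_accuracy = mean(majority == oracle))
}

#' Fit the min-max normalisation anchors
#'
#' Freezes the raw-score range of a declared reference tile set; CIF scores
#' are the clipped min-max normalisation of raw scores against these
#' anchors (order-preserving, ties preserved).
#'
#' @param model A trained `ranking_model`.
#' @param features Reference tile feature matrix.
#' @return The model with `norm_low` / `norm_high` set.
#' @export
calibrate_scores <- function(model, features) {
  s <- raw_scores(model, features)
  lo <- min(s); hi <- max(s)
  if (hi - lo < 1e-12) {
    stop("calibration error: reference raw scores are all equal",
         call. = FALSE)
  }
  model$norm_low <- lo
  model$norm_high <- hi
  model
}

#' Predict calibrated CIF scores
#'
#' @param model A calibrated `ranking_model`.
#' @param features Feature matrix for the tiles to score.
#' @return CIF scores in `[0, 1]`.
#' @export
predict_cif <- function(model, features) {
  if (!is.finite(model$norm_low) || !is.finite(model$norm_high)) {
    stop("calibration error: model has no normalisation anchors; ",
         "run calibrate_scores() first", call. = FALSE)
  }
  s <- raw_scores(model, features)
  clip01((s - model$norm_low) / (model$norm_high - model$norm_low))
}

# Pooled tile table for a list of samples: features, ground-truth tile
# severity and provenance. Tiles failing the inclusion filters are dropped.
build_tile_pool <- function(samples, size = 128L, stride = 64L,
                            backbone = cif_backbone()) {
  feats <- list(); sev <- list(); meta <- list()
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    grid <- extract_grid(smp$image, size, stride)
    grid <- apply_filters(grid, smp$layout)
    keep <- grid[grid$included, , drop = FALSE]
    if (nrow(keep) == 0) next
    f <- tile_features(smp$image, keep, backbone)
    rownames(f) <- paste0("s", i, "_", keep$tile_id)
    sv <- window_sums(integral_image(smp$severity_field),
                      keep$row0, keep$col0, size) / as.numeric(size)^2
    feats[[i]] <- f
    sev[[i]] <- sv
    meta[[i]] <- data.frame(tile_id = rownames(f), sample_index = i,
                            class_label = smp$class_label,
                            row0 = keep$row0, col0 = keep$col0)
  }
  features <- do.call(rbind, feats)
  list(features = features,
       severity = stats::setNames(unlist(sev), rownames(features)),
       meta = do.call(rbind, meta))
}

#' Train a ranking model over several human-in-the-loop rounds
#'
#' Reference training protocol: pools included tiles from the samples,
#' then alternates pair selection, (optionally noisy) annotator labeling
#' against the latent-severity oracle, and head training, and finally fixes
#' the min-max calibration on the pooled reference tiles.
#'
#' @param samples List of `synthetic_sample` objects.
#' @param rounds Number of training rounds.
#' @param pairs_per_round Pairs proposed per round.
#' @param size,stride Tile geometry.
#' @param strategy Pair-selection strategy after round 1 (round 1 is always
#'   uniform).
#' @param concordance,n_annotators Annotator simulation; `concordance = 1`
#'   reproduces the oracle exactly.
#' @param epochs,lr Head optimisation per round.
#' @param holdout_frac Held-out fraction within each round.
#' @param seed Run seed; all randomness (pair sampling, annotator noise,
#'   initialisation, splits) derives from it.
#' @return List with the calibrated `model`, `rounds` records,
#'   `final_heldout_accuracy` (final model on the union of held-out pairs
#'   from all rounds) and the tile `pool`.
#' @export
train_ranker <- function(samples, rounds = 3, pairs_per_round = 700,
                         size = 128L, stride = 64L,
                         strategy = "uniform",
                         concordance = 1.0, n_annotators = 3L,
                         epochs = 300, lr = 0.5, holdout_frac = 0.2,
                         seed = 1L) {
  pool <- build_tile_pool(samples, size, stride)
  seeds <- derive_seeds(seed, 3L * rounds + 1L)
  model <- new_ranking_model(seed = seeds[1])
  round_recs <- list()
  heldout_all <- list()
  for (r in seq_len(rounds)) {
    strat <- if (r == 1) "uniform" else strategy
    prs <- select_pairs(model, pool$features, pairs_per_round,
                        strategy = strat, seed = seeds[3 * r - 1])
    oracle <- as.integer(pool$severity[prs$tile_a_id] >=
                           pool$severity[prs$tile_b_id])
    if (concordance >= 1) {
      prs$label <- oracle
    } else {
      sim <- simulate_annotators(prs, oracle, concordance, n_annotators,
                                 seed = seeds[3 * r])
      prs <- sim$pairs
    }
    fit <- train_round(model, pool$features, prs, epochs = epochs, lr = lr,
                       holdout_frac = holdout_frac, seed = seeds[3 * r + 1])
    model <- fit$model
    round_recs[[r]] <- fit$round
    heldout_all[[r]] <- fit$round$heldout_pairs
  }
  model <- calibrate_scores(model, pool$features)
  held <- do.call(rbind, heldout_all)
  final_acc <- if (!is.null(held) && nrow(held) > 0) {
    sa <- raw_scores(model, pool$features[held$tile_a_id, , drop = FALSE])
    sb <- raw_scores(model, pool$features[held$tile_b_id, , drop = FALSE])
    pairwise_accuracy(sa, sb, held$label)
  } else NA_real_
  list(model = model, rounds = round_recs,
       final_heldout_accuracy = final_acc, pool = pool)
}
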