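# RankNet math, pair selection, annotator simulation, head training and
# score calibration.

test_that("pairwise probability is the logistic of the score difference", {
  expect_equal(pairwise_probability(1.3, 1.3), 0.5)
  expect_equal(pairwise_probability(log(3), 0), 0.75)
  expect_gt(pairwise_probability(60, 0), 1 - 1e-15)
  expect_error(pairwise_probability(NA, 1), "invalid-argument")
  expect_error(pairwise_probability(Inf, 1), "invalid-argument")
  set.seed(1)
  a <- rnorm(1000, sd = 4); b <- rnorm(1000, sd = 4)
  expect_equal(pairwise_probability(a, b) + pairwise_probability(b, a),
               rep(1, 1000))
})

test_that("pairwise loss matches the cross-entropy closed forms", {
  expect_equal(pairwise_loss(c(1, 0, 1), rep(0.5, 3)), log(2))
  expect_equal(pairwise_loss(1, 0.75), log(4 / 3))
  expect_lt(pairwise_loss(rep(1, 5), rep(1 - 1e-12, 5)), 1e-10)
  expect_error(pairwise_loss(numeric(0), numeric(0)), "empty")
  set.seed(2)
  expect_gte(pairwise_loss(rbinom(50, 1, 0.5), runif(50)), 0)
})

test_that("pair selection covers the two strategies deterministically", {
  feats <- matrix(0, 3, 10,
                  dimnames = list(c("t1", "t2", "t3"), NULL))
  feats[, 1] <- c(0, 0.01, 5)
  model <- new_ranking_model(seed = 1)
  model$w <- c(1, rep(0, 9))   # raw score = first feature

  two <- select_pairs(model, feats[1:2, ], 1, "uniform", seed = 1)
  expect_identical(sort(c(two$tile_a_id, two$tile_b_id)), c("t1", "t2"))

  unc <- select_pairs(model, feats, 1, "uncertainty")
  expect_identical(sort(c(unc$tile_a_id, unc$tile_b_id)), c("t1", "t2"))

  u1 <- select_pairs(model, feats, 3, "uniform", seed = 5)
  u2 <- select_pairs(model, feats, 3, "uniform", seed = 5)
  expect_identical(u1, u2)
  expect_warning(select_pairs(model, feats, 10, "uniform", seed = 1),
                 "truncated")
  expect_error(select_pairs(model, feats[1, , drop = FALSE], 1),
               "at least 2")
})

test_that("uniform selection enumerates every distinct pair exactly once", {
  feats <- matrix(rnorm(60), 6, 10,
                  dimnames = list(paste0("t", 1:6), NULL))
  model <- new_ranking_model()
  all_pairs <- select_pairs(model, feats, 15, "uniform", seed = 3)
  expect_identical(nrow(all_pairs), 15L)
  key <- apply(all_pairs, 1, function(r) paste(sort(r), collapse = "|"))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(all_pairs$tile_a_id != all_pairs$tile_b_id))
})

test_that("annotator simulation reproduces the binomial closed forms", {
  pairs <- data.frame(tile_a_id = paste0("a", 1:20000),
                      tile_b_id = paste0("b", 1:20000))
  oracle <- rep(c(0L, 1L), 10000)

  perfect <- simulate_annotators(pairs, oracle, concordance = 1, seed = 1)
  expect_identical(perfect$pairs$label, oracle)
  expect_equal(perfect$inter_annotator_agreement, 1)

  expect_error(simulate_annotators(pairs, oracle, concordance = 0.5),
               "concordance")

  # two independent raters at p = 0.884 agree with prob p^2 + (1-p)^2
  sim <- simulate_annotators(pairs, oracle, concordance = 0.884, seed = 2)
  expect_equal(sim$inter_annotator_agreement, 0.794912, tolerance = 0.015)

  # majority of three at p = 0.9: 3 p^2 (1-p) + p^3 = 0.972
  pairs10k <- pairs[1:10000, ]
  sim9 <- simulate_annotators(pairs10k, oracle[1:10000],
                              concordance = 0.9, seed = 3)
  expect_gte(sim9$majority_accuracy, 0.95)
  expect_lte(sim9$majority_accuracy, 0.99)
})

# Toy tile set whose mean brightness encodes severity: darker = more
# severe. Returns standardizable features for n constant patches.
brightness_toy <- function(n = 40, seed = 1) {
  set.seed(seed)
  sev <- seq(0.05, 0.95, length.out = n)
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    img <- matrix(255 * (1 - sev[i]) + rnorm(32 * 32, sd = 2), 32, 32)
    grid <- extract_grid(img, 32, 32)
    tile_features(img, grid)
  }))
  rownames(feats) <- paste0("p", seq_len(n))
  list(features = feats, severity = sev)
}

toy_pairs <- function(n_items, n_pairs, sev, seed = 1, shuffle = FALSE) {
  set.seed(seed)
  ia <- sample(n_items, n_pairs, replace = TRUE)
  ib <- sample(n_items, n_pairs, replace = TRUE)
  keep <- ia != ib
  ia <- ia[keep]; ib <- ib[keep]
  lab <- as.integer(sev[ia] >= sev[ib])
  if (shuffle) lab <- sample(lab)
  data.frame(tile_a_id = paste0("p", ia), tile_b_id = paste0("p", ib),
             label = lab)
}

test_that("zero epochs leave the model unchanged; degenerate pairs error", {
  toy <- brightness_toy()
  pairs <- toy_pairs(40, 100, toy$severity, seed = 4)
  model <- new_ranking_model(seed = 1)
  fit <- train_round(model, toy$features, pairs, epochs = 0, seed = 1)
  expect_identical(fit$model$w, model$w)
  expect_error(train_round(model, toy$features, pairs[0, ], seed = 1),
               "empty")
  degen <- data.frame(tile_a_id = "p1", tile_b_id = "p1", label = 1)
  expect_error(train_round(model, toy$features, degen, seed = 1),
               "training-data")
})

test_that("the head separates the brightness toy within five epochs", {
  toy <- brightness_toy()
  pairs <- toy_pairs(40, 1200, toy$severity, seed = 5)
  model <- new_ranking_model(seed = 1)
  fit <- train_round(model, toy$features, pairs, epochs = 5, lr = 2,
                     seed = 2)
  expect_gte(fit$round$heldout_accuracy, 0.95)
  expect_identical(fit$round$n_train + fit$round$n_heldout, nrow(pairs))
})

test_that("label-shuffled training stays at chance accuracy", {
  toy <- brightness_toy()
  pairs <- toy_pairs(40, 4200, toy$severity, seed = 6, shuffle = TRUE)
  model <- new_ranking_model(seed = 1)
  fit <- train_round(model, toy$features, pairs, epochs = 100,
                     holdout_frac = 0.3, seed = 3)
  expect_gte(fit$round$heldout_accuracy, 0.45)
  expect_lte(fit$round$heldout_accuracy, 0.55)
})

test_that("calibration maps the reference extremes to 0 and 1 and preserves order", {
  toy <- brightness_toy()
  pairs <- toy_pairs(40, 800, toy$severity, seed = 7)
  model <- new_ranking_model(seed = 1)
  model <- train_round(model, toy$features, pairs, epochs = 50,
                       seed = 4)$model
  expect_error(predict_cif(model, toy$features), "calibration")
  model <- calibrate_scores(model, toy$features)
  sc <- predict_cif(model, toy$features)
  raw <- cifmapr:::raw_scores(model, toy$features)
  expect_equal(unname(sc[which.max(raw)]), 1)
  expect_equal(unname(sc[which.min(raw)]), 0)
  expect_identical(order(sc), order(raw))
  # degenerate reference set
  flat <- matrix(1, 4, 10, dimnames = list(paste0("f", 1:4), NULL))
  expect_error(calibrate_scores(model, flat), "calibration error")
})

test_that("training is reproducible under a fixed run seed", {
  samples <- lapply(c(0.1, 0.45, 0.8), function(b)
    generate_sample(base_severity = b, shape = c(512, 512),
                    seed = round(1000 * b)))
  a <- train_ranker(samples, rounds = 2, pairs_per_round = 150,
                    epochs = 60, seed = 31)
  b <- train_ranker(samples, rounds = 2, pairs_per_round = 150,
                    epochs = 60, seed = 31)
  expect_identical(a$model$w, b$model$w)
  expect_identical(a$final_heldout_accuracy, b$final_heldout_accuracy)
})
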