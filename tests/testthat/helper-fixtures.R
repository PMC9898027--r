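# Shared fixtures. The reference ranking model (the three-round protocol
# on a severity-graded cohort) is expensive to train, so it is memoized
# and shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ten samples whose base severities span the full range; the training
# cohort of the reference protocol.
graded_training_samples <- function() {
  if (is.null(.fixture_cache$graded)) {
    bases <- seq(0.05, 0.75, length.out = 10)
    .fixture_cache$graded <- lapply(seq_along(bases), function(i)
      generate_sample(base_severity = bases[i], seed = 100 + i))
  }
  .fixture_cache$graded
}

# Reference three-round training run (oracle labels, uniform pairs).
get_reference_ranker <- function() {
  if (is.null(.fixture_cache$ranker)) {
    .fixture_cache$ranker <- train_ranker(graded_training_samples(),
                                          rounds = 3, pairs_per_round = 700,
                                          seed = 42)
  }
  .fixture_cache$ranker
}

# Held-out multi-class evaluation cohort (never used in training).
get_eval_cohort <- function() {
  if (is.null(.fixture_cache$eval)) {
    .fixture_cache$eval <- generate_cohort(n_per_class = 2, seed = 777)
  }
  .fixture_cache$eval
}

# Random score map with optional excluded (NA) cells.
random_map <- function(nr = 8, nc = 8, na_frac = 0) {
  v <- matrix(stats::runif(nr * nc), nr, nc)
  if (na_frac > 0) v[sample(nr * nc, round(na_frac * nr * nc))] <- NA
  v
}

# Number of bars alive at threshold t (birth >= t, not yet dead).
alive_at <- function(bc, t, d) {
  b <- bc[bc$dim == d, , drop = FALSE]
  sum(b$birth >= t & (is.na(b$death) | b$death < t))
}

# Tile-mean latent severity map of a sample (ground-truth analogue of a
# CIF map), on the demo grid geometry.
severity_tile_map <- function(sample, size = 128L, stride = 64L) {
  grid <- extract_grid(sample$severity_field, size, stride)
  ii <- cifmapr:::integral_image(sample$severity_field)
  vals <- cifmapr:::window_sums(ii, grid$row0, grid$col0, size) /
    as.numeric(size)^2
  gd <- attr(grid, "grid_dim")
  m <- matrix(NA_real_, gd[1], gd[2])
  m[cbind(grid$grid_row + 1L, grid$grid_col + 1L)] <- vals
  m
}
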