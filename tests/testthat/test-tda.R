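# Persistent homology of the super-level filtration: hand-enumerated
# fixtures, elder rule, oracle equivalence and barcode statistics.

test_that("a constant connected map has exactly one open component bar", {
  bc <- h0_barcode(matrix(0.5, 3, 4))
  expect_identical(nrow(bc), 1L)
  expect_equal(bc$birth, 0.5)
  expect_true(is.na(bc$death))
})

test_that("the 1x3 map [0.9, 0.1, 0.8] yields the hand-enumerated bars", {
  bc <- h0_barcode(matrix(c(0.9, 0.1, 0.8), nrow = 1))
  bc <- bc[order(-bc$birth), ]
  expect_identical(nrow(bc), 2L)
  expect_equal(bc$birth, c(0.9, 0.8))
  expect_true(is.na(bc$death[1]))
  expect_equal(bc$death[2], 0.1)
  # no holes on a path
  expect_identical(nrow(h1_barcode(matrix(c(0.9, 0.1, 0.8), nrow = 1))), 0L)
})

test_that("at a merge the younger component dies and ties break row-major", {
  bc <- h0_barcode(matrix(c(0.9, 0.3, 0.7), nrow = 1))
  open <- bc[is.na(bc$death), ]
  fin <- bc[!is.na(bc$death), ]
  expect_equal(open$birth, 0.9)
  expect_equal(c(fin$birth, fin$death), c(0.7, 0.3))
  # equal births: the earlier (row-major) cell survives
  bc2 <- h0_barcode(matrix(c(0.9, 0.1, 0.9), nrow = 1))
  open2 <- bc2[is.na(bc2$death), ]
  expect_identical(c(open2$birth_row, open2$birth_col), c(1, 1))
  fin2 <- bc2[!is.na(bc2$death), ]
  expect_equal(c(fin2$birth, fin2$death), c(0.9, 0.1))
})

test_that("the 5x5 ring yields exactly one dim-1 bar born 0.9 dying 0.1", {
  ring <- matrix(0.9, 5, 5)
  ring[2:4, 2:4] <- 0.1
  b1 <- h1_barcode(ring)
  expect_identical(nrow(b1), 1L)
  expect_equal(b1$birth, 0.9)
  expect_equal(b1$death, 0.1)
  orc <- brute_force_oracle(ring)
  expect_equal(orc$n_cycles[orc$threshold == 0.9], 1)
  expect_equal(orc$n_cycles[orc$threshold == 0.1], 0)
})

test_that("empty and oversized inputs are rejected", {
  expect_error(h0_barcode(matrix(NA_real_, 2, 2)), "empty-input")
  expect_error(h1_barcode(matrix(NA_real_, 2, 2)), "empty-input")
  expect_error(brute_force_oracle(matrix(0.5, 40, 40)), "guard")
})

test_that("the oracle counts components and cycles on enumerable fixtures", {
  orc <- brute_force_oracle(matrix(0.5, 3, 3))
  expect_identical(nrow(orc), 1L)
  expect_equal(orc$n_components, 1)
  expect_equal(orc$n_cycles, 0)
  cb <- matrix(0.1, 4, 4)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 0.9
  orc <- brute_force_oracle(cb)
  expect_equal(orc$n_components[orc$threshold == 0.9], 1)  # 8-connectivity
})

test_that("barcodes agree with the brute-force oracle on random grids", {
  set.seed(31)
  for (g in 1:60) {
    v <- matrix(sample(seq(0.05, 0.95, by = 0.05), 64, replace = TRUE),
                8, 8)
    if (g %% 3 == 0) v[sample(64, sample(3:10, 1))] <- NA
    bc0 <- h0_barcode(v)
    bc1 <- h1_barcode(v, keep_open = TRUE)
    orc <- brute_force_oracle(v)
    for (i in seq_len(nrow(orc))) {
      t <- orc$threshold[i]
      expect_identical(alive_at(bc0, t, 0), as.integer(orc$n_components[i]))
      expect_identical(alive_at(bc1, t, 1), as.integer(orc$n_cycles[i]))
    }
  }
})

test_that("holes around excluded cells are open bars counted as mask holes", {
  v <- matrix(0.8, 5, 5)
  v[3, 3] <- NA
  b1_default <- h1_barcode(v)
  expect_identical(nrow(b1_default), 0L)
  expect_identical(attr(b1_default, "mask_holes"), 1L)
  b1_open <- h1_barcode(v, keep_open = TRUE)
  expect_identical(nrow(b1_open), 1L)
  expect_true(is.na(b1_open$death))
})

test_that("tiny perturbations move bar endpoints by at most the perturbation", {
  set.seed(17)
  v <- matrix(sample(seq(0.02, 0.98, by = 0.02), 49), 7, 7)
  eps <- 1e-6
  delta <- matrix(runif(49, -eps, eps), 7, 7)
  for (dimn in 0:1) {
    b_fun <- if (dimn == 0) h0_barcode else h1_barcode
    b1 <- b_fun(v); b2 <- b_fun(v + delta)
    expect_identical(nrow(b1), nrow(b2))
    o1 <- order(b1$birth, b1$death); o2 <- order(b2$birth, b2$death)
    expect_true(all(abs(b1$birth[o1] - b2$birth[o2]) <= eps))
    fin <- !is.na(b1$death[o1])
    expect_true(all(abs(b1$death[o1][fin] - b2$death[o2][fin]) <= eps))
  }
})

test_that("barcode statistics follow their definitions", {
  empty <- data.frame(dim = integer(0), birth = numeric(0),
                      death = numeric(0))
  expect_true(all(barcode_features(empty) == 0))

  one <- data.frame(dim = 0L, birth = 0.9, death = 0.1)
  f <- barcode_features(one)
  expect_equal(unname(f["n_bars_dim0"]), 1)
  expect_equal(unname(f["total_persistence_dim0"]), 0.8)
  expect_equal(unname(f["max_persistence_dim0"]), 0.8)
  expect_equal(unname(f["n_hotspots_above"]), 1)
  expect_equal(unname(f["n_persistent_dim0"]), 1)

  # open bars: counted, excluded from persistence unless a floor is given
  open <- data.frame(dim = 0L, birth = c(0.9, 0.6), death = c(NA, 0.5))
  f2 <- barcode_features(open)
  expect_equal(unname(f2["n_bars_dim0"]), 2)
  expect_equal(unname(f2["total_persistence_dim0"]), 0.1)
  f3 <- barcode_features(open, death_floor = 0.2)
  expect_equal(unname(f3["total_persistence_dim0"]), 0.7 + 0.1)

  # persistence entropy of two equal bars is ln 2
  eq <- data.frame(dim = 1L, birth = c(0.8, 0.6), death = c(0.4, 0.2))
  expect_equal(unname(barcode_features(eq)["persistence_entropy_dim1"]),
               log(2))
})

test_that("prePMF-like severity maps carry more high-birth components than ET-like", {
  # fibers are irrelevant here: the map is the tile-mean latent severity,
  # with microfoci large enough to cover whole tiles so that hotspot
  # components are born above 0.75, and without clustering so that
  # distinct foci stay distinct components
  specs <- default_class_specs()[c("ET-like", "prePMF-like")]
  for (cl in names(specs)) {
    specs[[cl]]$hotspot_radius <- 96
    specs[[cl]]$hotspot_boost <- 0.7
    specs[[cl]]$hotspot_clustering <- 0
    specs[[cl]]$base_sd <- 0.04
    specs[[cl]]$field_amplitude <- 0.04
  }
  co <- generate_cohort(specs, n_per_class = 8, seed = 99,
                        params = fiber_field_params(fiber_density = 0))
  lab <- vapply(co, `[[`, character(1), "class_label")
  nh <- vapply(co, function(s) {
    bc <- compute_barcode(severity_tile_map(s))
    unname(barcode_features(bc, hotspot_threshold = 0.75)["n_hotspots_above"])
  }, numeric(1))
  p <- suppressWarnings(
    wilcox.test(nh[lab == "ET-like"], nh[lab == "prePMF-like"],
                alternative = "less")$p.value)
  expect_lt(p, 0.01)
})
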