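# Synthetic reticulin generator: determinism, severity semantics, layout
# exclusivity and the latent-severity oracle.

test_that("zero fiber density gives a pure background with no fiber pixels", {
  p <- fiber_field_params(fiber_density = 0, noise_sd = 0)
  s <- generate_sample(params = p, shape = c(256, 256),
                       layout_fracs = c(fat = 0, bone = 0, vessel = 0),
                       field_amplitude = 0, seed = 3)
  expect_true(all(s$image == p$background_gray))
  thr <- (p$background_gray + p$fiber_gray) / 2
  expect_identical(sum(s$image < thr), 0L)
})

test_that("identical seed and parameters reproduce samples and cohorts", {
  a <- generate_sample(base_severity = 0.3, shape = c(320, 320), seed = 9)
  b <- generate_sample(base_severity = 0.3, shape = c(320, 320), seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$severity_field, b$severity_field)
  expect_identical(a$layout, b$layout)
  c1 <- generate_cohort(n_per_class = 1, seed = 5, shape = c(320, 320))
  c2 <- generate_cohort(n_per_class = 1, seed = 5, shape = c(320, 320))
  expect_identical(lapply(c1, `[[`, "image"), lapply(c2, `[[`, "image"))
})

test_that("invalid arguments are rejected", {
  expect_error(generate_sample(shape = c(0, 100)), "invalid-argument")
  expect_error(generate_sample(layout_fracs = c(fat = 0.7, bone = 0.4,
                                                vessel = 0.2)),
               "invalid-argument")
  expect_error(fiber_field_params(fiber_gray = 220, background_gray = 200),
               "invalid-argument")
  expect_error(hotspot_spec(severity_boost = 1.2), "invalid-argument")
  expect_error(generate_cohort(n_per_class = 0), "invalid-argument")
  bad <- list("not-a-class" = default_class_specs()[["ET-like"]])
  expect_error(generate_cohort(bad, n_per_class = 1), "unknown class")
})

test_that("doubling severity strictly increases the fiber-pixel fraction", {
  dark_frac <- function(sev, seed) {
    p <- fiber_field_params(noise_sd = 0)
    s <- generate_sample(params = p, shape = c(1024, 1024),
                         base_severity = sev, field_amplitude = 0,
                         layout_fracs = c(fat = 0, bone = 0, vessel = 0),
                         seed = seed)
    mean(s$image < (p$background_gray + p$fiber_gray) / 2)
  }
  lo <- vapply(1:10, function(i) dark_frac(0.25, i), numeric(1))
  hi <- vapply(1:10, function(i) dark_frac(0.50, i), numeric(1))
  expect_true(all(hi > lo))
})

test_that("fiber fraction is monotone in density and thickness", {
  frac <- function(params, seed) {
    s <- generate_sample(params = params, shape = c(384, 384),
                         base_severity = 0.4, field_amplitude = 0,
                         layout_fracs = c(fat = 0, bone = 0, vessel = 0),
                         seed = seed)
    mean(s$image < 130)
  }
  seeds <- 1:10
  f_lo <- vapply(seeds, function(i)
    frac(fiber_field_params(fiber_density = 1500, noise_sd = 0), i),
    numeric(1))
  f_hi <- vapply(seeds, function(i)
    frac(fiber_field_params(fiber_density = 3000, noise_sd = 0), i),
    numeric(1))
  expect_lt(wilcox.test(f_lo, f_hi, alternative = "less")$p.value, 0.01)
  t_lo <- vapply(seeds, function(i)
    frac(fiber_field_params(thickness_mean = 1.5, noise_sd = 0), i),
    numeric(1))
  t_hi <- vapply(seeds, function(i)
    frac(fiber_field_params(thickness_mean = 3.0, noise_sd = 0), i),
    numeric(1))
  p_th <- suppressWarnings(
    wilcox.test(t_lo, t_hi, alternative = "less")$p.value)
  expect_lt(p_th, 0.01)
})

test_that("tissue layout masks are mutually exclusive subsets of the extent", {
  for (seed in c(2, 17, 31)) {
    s <- generate_sample(shape = c(512, 512), seed = seed)
    l <- s$layout
    expect_identical(sum(l$fat_mask & l$bone_mask), 0L)
    expect_identical(sum(l$fat_mask & l$vessel_mask), 0L)
    expect_identical(sum(l$bone_mask & l$vessel_mask), 0L)
    expect_identical(l$tissue_mask,
                     !(l$fat_mask | l$bone_mask | l$vessel_mask))
  }
})

test_that("hotspots raise severity by the boost, clipped at one", {
  base <- 0.2
  s0 <- generate_sample(base_severity = base, field_amplitude = 0,
                        shape = c(384, 384), seed = 8)
  expect_true(all(s0$severity_field == base))
  hs <- hotspot_spec(count = 1, radius_px = 40, severity_boost = 0.5)
  s1 <- generate_sample(hotspots = hs, base_severity = base,
                        field_amplitude = 0, shape = c(384, 384), seed = 8)
  expect_equal(max(s1$severity_field), base + 0.5)
  expect_equal(min(s1$severity_field), base)
  # clipping at 1
  s2 <- generate_sample(hotspots = hotspot_spec(1, 40, 0.6),
                        base_severity = 0.8, field_amplitude = 0,
                        shape = c(384, 384), seed = 8)
  expect_equal(max(s2$severity_field), 1)
})

test_that("ET-like cohorts carry fewer fiber pixels than MF-like cohorts", {
  specs <- default_class_specs()[c("ET-like", "MF-like")]
  co <- generate_cohort(specs, n_per_class = 3, seed = 12,
                        shape = c(512, 512))
  lab <- vapply(co, `[[`, character(1), "class_label")
  df <- vapply(co, function(s) mean(s$image < 130), numeric(1))
  expect_lt(mean(df[lab == "ET-like"]), mean(df[lab == "MF-like"]))
})

test_that("severity oracle ranks hotspot tiles above background and breaks ties toward a", {
  hs <- hotspot_spec(count = 1, radius_px = 80, severity_boost = 0.6)
  s <- generate_sample(hotspots = hs, base_severity = 0.1,
                       field_amplitude = 0, shape = c(512, 512), seed = 4)
  ctr <- s$hotspot_centers[1, ]
  hot <- list(row0 = max(0, round(ctr[1]) - 64),
              col0 = max(0, round(ctr[2]) - 64), size = 128)
  # find a background tile away from the hotspot
  bg <- if (ctr[1] > 256) list(row0 = 0, col0 = 0, size = 128) else
    list(row0 = 384, col0 = 384, size = 128)
  expect_identical(severity_oracle(hot, bg, s), "a_more_severe")
  expect_identical(severity_oracle(bg, hot, s), "b_more_severe")
  expect_identical(severity_oracle(bg, bg, s), "a_more_severe")
  out <- list(row0 = 500, col0 = 0, size = 128)
  expect_error(severity_oracle(out, bg, s), "out-of-bounds")
})

test_that("oracle follows a left-to-right severity gradient on 100 pairs", {
  ramp <- matrix(rep(seq(0, 1, length.out = 512), each = 512), 512, 512)
  s <- generate_sample(base_severity = ramp, field_amplitude = 0,
                       shape = c(512, 512),
                       params = fiber_field_params(fiber_density = 0),
                       seed = 2)
  grid <- extract_grid(s$image, 128, 64)
  set.seed(10)
  correct <- 0L
  for (k in 1:100) {
    ij <- sample(nrow(grid), 2)
    ta <- as.list(grid[ij[1], ]); ta$size <- 128
    tb <- as.list(grid[ij[2], ]); tb$size <- 128
    if (ta$col0 == tb$col0) { correct <- correct + 1L; next }
    lab <- severity_oracle(ta, tb, s)
    want <- if (ta$col0 > tb$col0) "a_more_severe" else "b_more_severe"
    if (lab == want) correct <- correct + 1L
  }
  expect_identical(correct, 100L)
})
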