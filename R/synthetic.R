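# Synthetic reticulin-stained-like image generator. Every downstream stage
# (tiling, ranking, mapping, topology, cohort analysis) is testable against
# the latent per-pixel severity field this module produces.

#' Fiber-field parameters
#'
#' Parameters of the synthetic reticulin fiber network. Severity cues follow
#' reticulin histology: more severe fibrosis shows more fibers, thicker
#' fibers and more frequent crossings; silver-stained reticulin appears as
#' dark linear material on a paler background.
#'
#' @param fiber_density Expected candidate fibers per megapixel at maximal
#'   severity. Candidates are thinned by local severity, so realised density
#'   increases with the latent severity field.
#' @param thickness_mean Mean fiber thickness in pixels (before the local
#'   severity scaling).
#' @param thickness_sd Standard deviation of fiber thickness in pixels.
#' @param intersection_bias Dimensionless >= 0. With probability
#'   `bias / (1 + bias)` a new fiber is seeded near an existing fiber,
#'   raising the crossing frequency.
#' @param background_gray Background intensity, 0-255.
#' @param fiber_gray Fiber intensity, 0-255; must be darker than the
#'   background.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed used by [generate_sample()] unless overridden.
#' @return A list of class `fiber_field_params`.
#' @export
fiber_field_params <- function(fiber_density = 4500, thickness_mean = 2.0,
                               thickness_sd = 0.5, intersection_bias = 0.5,
                               background_gray = 205, fiber_gray = 55,
                               noise_sd = 8, seed = 1L) {
  if (fiber_density < 0) stop_invalid("fiber_density must be >= 0")
  if (thickness_mean <= 0) stop_invalid("thickness_mean must be > 0")
  if (thickness_sd < 0) stop_invalid("thickness_sd must be >= 0")
  if (intersection_bias < 0) stop_invalid("intersection_bias must be >= 0")
  if (fiber_gray >= background_gray) {
    stop_invalid("fiber_gray must be < background_gray (fibers are dark)")
  }
  structure(list(fiber_density = fiber_density,
                 thickness_mean = thickness_mean,
                 thickness_sd = thickness_sd,
                 intersection_bias = intersection_bias,
                 background_gray = background_gray,
                 fiber_gray = fiber_gray,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fiber_field_params")
}

#' Hotspot specification
#'
#' Spatially clustered microfoci of advanced fibrosis: disks where the
#' latent severity is raised by `severity_boost` (clipped at 1).
#'
#' @param count Number of hotspots (>= 0).
#' @param radius_px Hotspot radius in pixels.
#' @param severity_boost Additive severity increment in `[0, 1]` applied on
#'   the union of the hotspot disks.
#' @param clustering Dimensionless >= 0. 0 places hotspots uniformly;
#'   larger values place new hotspots preferentially near existing ones
#'   (Matern-style parent/offspring placement).
#' @return A list of class `hotspot_spec`.
#' @export
hotspot_spec <- function(count = 0L, radius_px = 48, severity_boost = 0.6,
                         clustering = 0) {
  if (count < 0) stop_invalid("count must be >= 0")
  if (radius_px <= 0) stop_invalid("radius_px must be > 0")
  if (severity_boost < 0 || severity_boost > 1) {
    stop_invalid("severity_boost must be in [0, 1]")
  }
  if (clustering < 0) stop_invalid("clustering must be >= 0")
  structure(list(count = as.integer(count), radius_px = radius_px,
                 severity_boost = severity_boost, clustering = clustering),
            class = "hotspot_spec")
}

# Smooth mean-zero random field by bilinear upsampling of a coarse iid
# normal grid; models within-sample spatial variation of fibrosis.
smooth_field <- function(shape, scale_px = 96, amplitude = 0.08) {
  if (amplitude == 0) return(matrix(0, shape[1], shape[2]))
  nr <- max(2L, ceiling(shape[1] / scale_px) + 1L)
  nc <- max(2L, ceiling(shape[2] / scale_px) + 1L)
  coarse <- matrix(stats::rnorm(nr * nc), nr, nc)
  # bilinear interpolation onto the pixel grid
  ri <- seq(1, nr, length.out = shape[1])
  ci <- seq(1, nc, length.out = shape[2])
  r0 <- pmin(floor(ri), nr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); fc <- ci - c0
  # interpolate rows first, then columns
  rows_interp <- coarse[r0, , drop = FALSE] * (1 - fr) +
    coarse[r0 + 1, , drop = FALSE] * fr
  fcv <- rep(fc, each = shape[1])
  v <- rows_interp[, c0, drop = FALSE] * (1 - fcv) +
    rows_interp[, c0 + 1, drop = FALSE] * fcv
  amplitude * v
}

# Linear pixel indices of a thick segment ("capsule"): points within
# halfw of the segment p1--p2. Coordinates are (row, col), 1-based.
capsule_pixels <- function(p1, p2, halfw, shape) {
  lo <- pmax(1, floor(pmin(p1, p2) - halfw - 1))
  hi <- pmin(shape, ceiling(pmax(p1, p2) + halfw + 1))
  if (any(hi < lo)) return(integer(0))
  rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
  qr <- rep(rows, times = length(cols))
  qc <- rep(cols, each = length(rows))
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (qr - p1[1])^2 + (qc - p1[2])^2
  } else {
    t <- ((qr - p1[1]) * d[1] + (qc - p1[2]) * d[2]) / len2
    t <- pmin(1, pmax(0, t))
    dist2 <- (qr - (p1[1] + t * d[1]))^2 + (qc - (p1[2] + t * d[2]))^2
  }
  keep <- dist2 <= halfw^2
  (qc[keep] - 1L) * shape[1] + qr[keep]
}

disk_pixels <- function(center, radius, shape) {
  capsule_pixels(center, center, radius, shape)
}

# Tissue layout: mutually exclusive fat / bone / vessel masks plus the
# remaining analyzable tissue. Vessels are drawn as walls around a lumen;
# the mask covers the whole vessel footprint.
generate_layout <- function(shape, fracs) {
  npx <- prod(shape)
  bone <- matrix(FALSE, shape[1], shape[2])
  fat <- matrix(FALSE, shape[1], shape[2])
  vessel <- matrix(FALSE, shape[1], shape[2])
  ring <- matrix(FALSE, shape[1], shape[2])
  target <- function(name) if (name %in% names(fracs)) fracs[[name]] else 0
  # bony trabeculae: elongated capsules
  tb <- target("bone")
  it <- 0; covered <- 0
  while (covered / npx < tb && it < 60) {
    it <- it + 1
    c0 <- stats::runif(2) * shape
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.15, 0.4) * min(shape)
    hw <- stats::runif(1, 8, 16)
    dvec <- c(cos(ang), sin(ang)) * len / 2
    px <- capsule_pixels(c0 - dvec, c0 + dvec, hw, shape)
    px <- px[!bone[px]]
    bone[px] <- TRUE
    covered <- covered + length(px)
  }
  # fat vacuoles: round droplets, excluded from bone
  tf <- target("fat")
  it <- 0; covered <- 0
  while (covered / npx < tf && it < 400) {
    it <- it + 1
    px <- disk_pixels(stats::runif(2) * shape, stats::runif(1, 6, 18), shape)
    px <- px[!bone[px] & !fat[px]]
    fat[px] <- TRUE
    covered <- covered + length(px)
  }
  # vessels: annular walls with a lumen, excluded from bone and fat
  tv <- target("vessel")
  it <- 0; covered <- 0
  while (covered / npx < tv && it < 120) {
    it <- it + 1
    c0 <- stats::runif(2) * shape
    r <- stats::runif(1, 12, 26)
    wall <- stats::runif(1, 3, 5)
    px <- disk_pixels(c0, r, shape)
    px <- px[!bone[px] & !fat[px] & !vessel[px]]
    inner <- disk_pixels(c0, r - wall, shape)
    vessel[px] <- TRUE
    covered <- covered + length(px)
    ring[setdiff(px, inner)] <- TRUE
  }
  tissue <- !(fat | bone | vessel)
  list(fat_mask = fat, bone_mask = bone, vessel_mask = vessel,
       tissue_mask = tissue, vessel_wall = ring)
}

#' Generate one synthetic reticulin-like sample
#'
#' Builds a latent per-pixel severity field (constant or caller-supplied
#' base, plus a smooth spatial variation and hotspot disks), a tissue layout
#' (fat vacuoles, bony trabeculae, vessels), and renders a grayscale image
#' in which local fiber density, thickness and crossing frequency increase
#' with local severity.
#'
#' @param params A [fiber_field_params()] object.
#' @param hotspots A [hotspot_spec()] object.
#' @param layout_fracs Named numeric vector with target area fractions for
#'   `fat`, `bone` and `vessel`; must sum to at most 1.
#' @param shape Image dimensions `c(rows, cols)` in pixels.
#' @param base_severity Scalar in `[0, 1]`, or a matrix of `shape` giving
#'   the per-pixel base severity (e.g. a gradient for oracle tests).
#' @param field_amplitude Amplitude of the smooth within-sample severity
#'   variation (0 disables it).
#' @param field_scale Correlation scale of that variation, pixels.
#' @param class_label Free-text class label stored with the sample.
#' @param seed Integer seed; defaults to `params$seed`. Identical seed and
#'   parameters give bit-identical samples.
#' @return A list of class `synthetic_sample` with elements `image` (numeric
#'   matrix, 0-255), `layout` (list of logical masks), `severity_field`
#'   (matrix in `[0, 1]`), `class_label`, `seed`, `params`, `hotspots` and
#'   `hotspot_centers`.
#' @export
generate_sample <- function(params = fiber_field_params(),
                            hotspots = hotspot_spec(),
                            layout_fracs = c(fat = 0.08, bone = 0.04,
                                             vessel = 0.02),
                            shape = c(768, 768),
                            base_severity = 0.15,
                            field_amplitude = 0.08,
                            field_scale = 96,
                            class_label = "unlabeled",
                            seed = params$seed) {
  if (length(shape) != 2 || any(shape <= 0)) {
    stop_invalid("shape must be two positive extents")
  }
  shape <- as.integer(shape)
  if (sum(layout_fracs) > 1) stop_invalid("mask fractions sum to > 1")
  if (is.matrix(base_severity)) {
    if (!all(dim(base_severity) == shape)) {
      stop_invalid("base_severity matrix must match shape")
    }
  } else if (length(base_severity) != 1) {
    stop_invalid("base_severity must be a scalar or a matrix")
  }
  if (any(base_severity < 0 | base_severity > 1)) {
    stop_invalid("base_severity must lie in [0, 1]")
  }

  with_seed(seed, {
    sev <- if (is.matrix(base_severity)) base_severity else
      matrix(base_severity, shape[1], shape[2])
    sev <- sev + smooth_field(shape, field_scale, field_amplitude)

    centers <- NULL
    if (hotspots$count > 0) {
      boost_mask <- matrix(FALSE, shape[1], shape[2])
      centers <- matrix(0, hotspots$count, 2)
      margin <- hotspots$radius_px
      for (i in seq_len(hotspots$count)) {
        near_existing <- i > 1 && hotspots$clustering > 0 &&
          stats::runif(1) < hotspots$clustering / (1 + hotspots$clustering)
        if (near_existing) {
          parent <- centers[sample.int(i - 1L, 1), ]
          c0 <- parent + stats::rnorm(2, sd = 2 * hotspots$radius_px)
          c0 <- pmin(pmax(c0, margin), shape - margin)
        } else {
          c0 <- margin + stats::runif(2) * (shape - 2 * margin)
        }
        centers[i, ] <- c0
        boost_mask[disk_pixels(c0, hotspots$radius_px, shape)] <- TRUE
      }
      sev[boost_mask] <- sev[boost_mask] + hotspots$severity_boost
    }
    sev <- clip01(sev)

    layout <- generate_layout(shape, layout_fracs)

    # fibers: Poisson number of candidates, thinned by local severity;
    # thickness grows with local severity; intersection_bias reseeds new
    # fibers near existing ones
    fiber <- matrix(FALSE, shape[1], shape[2])
    n_cand <- stats::rpois(1, params$fiber_density / 1e6 * prod(shape))
    accepted_mid <- matrix(0, n_cand, 2)
    n_acc <- 0L
    p_bias <- params$intersection_bias / (1 + params$intersection_bias)
    for (i in seq_len(n_cand)) {
      if (n_acc > 0 && stats::runif(1) < p_bias) {
        base <- accepted_mid[sample.int(n_acc, 1), ]
        mid <- pmin(pmax(base + stats::rnorm(2, sd = 25), 1), shape)
      } else {
        mid <- 1 + stats::runif(2) * (shape - 1)
      }
      s_here <- sev[floor(mid[1]), floor(mid[2])]
      if (stats::runif(1) > 0.05 + 0.95 * s_here) next
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 30, 90)
      th <- max(0.6, stats::rnorm(1, params$thickness_mean *
                                    (0.6 + 0.8 * s_here),
                                  params$thickness_sd))
      dvec <- c(cos(ang), sin(ang)) * len / 2
      px <- capsule_pixels(mid - dvec, mid + dvec, th / 2, shape)
      px <- px[layout$tissue_mask[px]]
      fiber[px] <- TRUE
      n_acc <- n_acc + 1L
      accepted_mid[n_acc, ] <- mid
    }

    img <- matrix(params$background_gray, shape[1], shape[2])
    img[fiber] <- params$fiber_gray
    img[layout$fat_mask] <- 243
    img[layout$bone_mask] <- 155
    img[layout$vessel_mask] <- 225
    img[layout$vessel_wall] <- 80
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(prod(shape), sd = params$noise_sd)
    }
    img <- clip_range(img, 0, 255)

    structure(list(image = img,
                   layout = layout[c("fat_mask", "bone_mask", "vessel_mask",
                                     "tissue_mask")],
                   severity_field = sev,
                   class_label = class_label,
                   seed = as.integer(seed),
                   params = params,
                   hotspots = hotspots,
                   hotspot_centers = centers),
              class = "synthetic_sample")
  })
}

#' Default synthetic class presets
#'
#' Study conditions for the five synthetic classes. ET-like and prePMF-like
#' share the same base-severity distribution and differ only in hotspot
#' prevalence and clustering, so that their separation must come from the
#' spatial arrangement of high scores rather than mean severity.
#'
#' @return Named list of per-class parameter distributions.
#' @export
default_class_specs <- function() {
  list(
    "reactive" = list(base_mean = 0.05, base_sd = 0.03,
                      field_amplitude = 0.04,
                      hotspot_count = c(0L, 0L), hotspot_radius = 48,
                      hotspot_boost = 0.6, hotspot_clustering = 0),
    "ET-like" = list(base_mean = 0.15, base_sd = 0.08,
                     field_amplitude = 0.08,
                     hotspot_count = c(0L, 1L), hotspot_radius = 48,
                     hotspot_boost = 0.6, hotspot_clustering = 0),
    "PV-like" = list(base_mean = 0.30, base_sd = 0.08,
                     field_amplitude = 0.10,
                     hotspot_count = c(0L, 2L), hotspot_radius = 48,
                     hotspot_boost = 0.5, hotspot_clustering = 0),
    "prePMF-like" = list(base_mean = 0.15, base_sd = 0.08,
                         field_amplitude = 0.08,
                         hotspot_count = c(2L, 5L), hotspot_radius = 48,
                         hotspot_boost = 0.6, hotspot_clustering = 1.5),
    "MF-like" = list(base_mean = 0.55, base_sd = 0.10,
                     field_amplitude = 0.12,
                     hotspot_count = c(1L, 3L), hotspot_radius = 64,
                     hotspot_boost = 0.35, hotspot_clustering = 0.5)
  )
}

#' Generate a seeded synthetic cohort
#'
#' @param class_specs Named list of class presets as returned by
#'   [default_class_specs()]; names must be drawn from the five canonical
#'   labels.
#' @param n_per_class Samples per class (>= 1).
#' @param seed Cohort seed; per-sample seeds are derived deterministically.
#' @param shape,params,layout_fracs Passed to [generate_sample()].
#' @return List of `synthetic_sample` objects with `class_label` set.
#' @export
generate_cohort <- function(class_specs = default_class_specs(),
                            n_per_class = 5, seed = 1L,
                            shape = c(768, 768),
                            params = fiber_field_params(),
                            layout_fracs = c(fat = 0.08, bone = 0.04,
                                             vessel = 0.02)) {
  if (n_per_class < 1) stop_invalid("n_per_class must be >= 1")
  known <- names(default_class_specs())
  if (is.null(names(class_specs)) || !all(names(class_specs) %in% known)) {
    stop_invalid("unknown class label; expected one of: ",
                 paste(known, collapse = ", "))
  }
  labels <- rep(names(class_specs), each = n_per_class)
  n <- length(labels)
  seeds <- derive_seeds(seed, 2L * n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- class_specs[[labels[i]]]
    draw <- with_seed(seeds[i], {
      base <- min(0.95, max(0.02, stats::rnorm(1, spec$base_mean,
                                               spec$base_sd)))
      cnt <- if (spec$hotspot_count[2] > spec$hotspot_count[1]) {
        sample(spec$hotspot_count[1]:spec$hotspot_count[2], 1)
      } else spec$hotspot_count[1]
      list(base = base, cnt = cnt)
    })
    hs <- hotspot_spec(count = draw$cnt, radius_px = spec$hotspot_radius,
                       severity_boost = spec$hotspot_boost,
                       clustering = spec$hotspot_clustering)
    out[[i]] <- generate_sample(params = params, hotspots = hs,
                                layout_fracs = layout_fracs, shape = shape,
                                base_severity = draw$base,
                                field_amplitude = spec$field_amplitude,
                                class_label = labels[i],
                                seed = seeds[n + i])
  }
  out
}

# Mean latent severity over one tile footprint (0-based anchor, half-open
# window), with bounds checking.
tile_mean_severity <- function(sample, row0, col0, size) {
  sev <- sample$severity_field
  if (row0 < 0 || col0 < 0 || row0 + size > nrow(sev) ||
      col0 + size > ncol(sev)) {
    stop("out-of-bounds: tile extends outside the sample extent",
         call. = FALSE)
  }
  mean(sev[(row0 + 1):(row0 + size), (col0 + 1):(col0 + size)])
}

#' Severity oracle for a tile pair
#'
#' Stand-in for expert pairwise review: compares the mean latent severity
#' over the two tile footprints. Exact ties are deterministically broken
#' toward the first tile.
#'
#' @param tile_a,tile_b Lists or one-row data frames with `row0`, `col0`
#'   (0-based top-left pixel) and `size`.
#' @param sample A `synthetic_sample`.
#' @return `"a_more_severe"` or `"b_more_severe"`.
#' @export
severity_oracle <- function(tile_a, tile_b, sample) {
  ma <- tile_mean_severity(sample, tile_a$row0, tile_a$col0, tile_a$size)
  mb <- tile_mean_severity(sample, tile_b$row0, tile_b$col0, tile_b$size)
  if (ma >= mb) "a_more_severe" else "b_more_severe"
}
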