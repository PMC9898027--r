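# Per-sample CIF maps and the fibrosis feature vector: average score,
# four-bin tile distribution and Shannon-entropy heterogeneity; plus
# false-color overlays and the radar-axis summary.

#' Build a CIF map for one sample
#'
#' Scores every included tile of a filtered grid with a calibrated ranking
#' model and arranges the scores on the tile-index grid; excluded tiles are
#' `NA`.
#'
#' @param model Calibrated `ranking_model`.
#' @param grid A `tile_grid` with `included` flags (see [apply_filters()]).
#' @param image Grayscale matrix the grid was extracted from.
#' @return A numeric matrix of class `cif_map` (grid rows x grid cols) with
#'   attributes `size`, `stride`, `image_shape` and `positions`.
#' @export
build_cif_map <- function(model, grid, image) {
  if (is.null(grid$included)) stop_invalid("grid has no inclusion flags")
  inc <- grid[grid$included, , drop = FALSE]
  if (nrow(inc) == 0) {
    stop("empty-map error: no included tiles", call. = FALSE)
  }
  feats <- tile_features(image, inc, model$backbone)
  scores <- predict_cif(model, feats)
  gd <- attr(grid, "grid_dim")
  m <- matrix(NA_real_, gd[1], gd[2])
  m[cbind(inc$grid_row + 1L, inc$grid_col + 1L)] <- scores
  structure(m, size = attr(grid, "size"), stride = attr(grid, "stride"),
            image_shape = attr(grid, "image_shape"),
            positions = grid[, c("tile_id", "grid_row", "grid_col",
                                 "row0", "col0")],
            class = c("cif_map", "matrix", "array"))
}

# A cif_map built directly from a score matrix (used by IO and tests).
as_cif_map <- function(scores, size = NA_integer_, stride = NA_integer_) {
  structure(scores, size = size, stride = stride,
            class = c("cif_map", "matrix", "array"))
}

#' Four-bin tile-score distribution
#'
#' Bins are half-open `[edge_k, edge_k+1)` with the last bin closed at 1,
#' so a score of exactly 1 counts in the top bin.
#'
#' @param map A `cif_map` (or plain matrix of scores with `NA` for
#'   excluded tiles).
#' @param edges Five ascending cut points spanning `[0, 1]`.
#' @return Numeric vector `p0..p3` summing to 1.
#' @export
bin_distribution <- function(map, edges = c(0, 0.25, 0.5, 0.75, 1)) {
  if (length(edges) != 5 || edges[1] != 0 || edges[5] != 1 ||
      any(diff(edges) <= 0)) {
    stop_invalid("edges must be 5 strictly increasing cuts from 0 to 1")
  }
  x <- map[!is.na(map)]
  if (length(x) == 0) stop("empty-map error: no scores", call. = FALSE)
  counts <- vapply(seq_len(4), function(k) {
    if (k < 4) sum(x >= edges[k] & x < edges[k + 1])
    else sum(x >= edges[k] & x <= edges[k + 1])
  }, numeric(1))
  stats::setNames(counts / length(x), paste0("p", 0:3))
}

#' Shannon-entropy heterogeneity of a bin distribution
#'
#' `H = -sum(p_k log p_k) / log(K)` with `0 log 0 := 0`, normalised by the
#' number of bins so `H` lies in `[0, 1]`: 0 for a point mass, 1 for the
#' uniform distribution.
#'
#' @param p Bin probabilities (must be non-negative and sum to 1).
#' @return Scalar heterogeneity in `[0, 1]`.
#' @export
heterogeneity <- function(p) {
  if (any(p < 0)) stop_invalid("negative bin probability")
  if (abs(sum(p) - 1) > 1e-9) stop_invalid("bin probabilities must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(length(p))
}

#' Average CIF score of a map
#'
#' @param map A `cif_map`.
#' @return Arithmetic mean of the included tile scores.
#' @export
average_cif <- function(map) {
  x <- map[!is.na(map)]
  if (length(x) == 0) stop("empty-map error: no scores", call. = FALSE)
  mean(x)
}

#' Per-sample fibrosis feature vector
#'
#' @param map A `cif_map`.
#' @param edges Bin edges, see [bin_distribution()].
#' @return A list of class `sample_features`: `avg_cif`, `bin_fracs`,
#'   `heterogeneity`, `n_tiles`.
#' @export
sample_features <- function(map, edges = c(0, 0.25, 0.5, 0.75, 1)) {
  p <- bin_distribution(map, edges)
  structure(list(avg_cif = average_cif(map), bin_fracs = p,
                 heterogeneity = heterogeneity(p),
                 n_tiles = sum(!is.na(map))),
            class = "sample_features")
}

#' Radar-axis summary of a feature vector
#'
#' Fixed documented axis order: average CIF, the four bin fractions, then
#' heterogeneity. Values are passed through unchanged, so the radar axes
#' always match [bin_distribution()] and [heterogeneity()] exactly.
#'
#' @param fv A `sample_features` object.
#' @return Named numeric vector of length 6.
#' @export
radar_features <- function(fv) {
  c(avg_cif = fv$avg_cif,
    stats::setNames(as.numeric(fv$bin_fracs), paste0("p", 0:3)),
    heterogeneity = fv$heterogeneity)
}

# Per-pixel score field: mean of the scores of all included tiles covering
# each pixel (NA where no included tile covers). Shared by the overlay
# renderer and its tests.
overlay_score_field <- function(map, shape = attr(map, "image_shape")) {
  pos <- attr(map, "positions")
  size <- attr(map, "size")
  if (is.null(pos) || is.null(shape)) {
    stop_invalid("map lacks position metadata")
  }
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(pos))) {
    s <- map[pos$grid_row[i] + 1L, pos$grid_col[i] + 1L]
    if (is.na(s)) next
    rr <- (pos$row0[i] + 1L):(pos$row0[i] + size)
    cc <- (pos$col0[i] + 1L):(pos$col0[i] + size)
    acc[rr, cc] <- acc[rr, cc] + s
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Render a false-color CIF overlay
#'
#' Overlapping tiles (stride < size) are averaged per pixel before
#' colorization; pixels not covered by any included tile are left unshaded.
#'
#' @param map A `cif_map` built by [build_cif_map()].
#' @param image The original grayscale image (0-255).
#' @param palette Character vector of colors ramped over score 0..1.
#' @param alpha Overlay opacity in `[0, 1]`; 0 returns the input image.
#' @return `rows x cols x 3` numeric array, 0-255.
#' @export
render_overlay <- function(map, image,
                           palette = grDevices::hcl.colors(64, "viridis"),
                           alpha = 0.5) {
  shape <- attr(map, "image_shape")
  if (!all(dim(image) == shape)) {
    stop_invalid("image shape does not match the map's image shape")
  }
  field <- overlay_score_field(map, shape)
  ramp <- grDevices::colorRamp(palette)
  out <- array(rep(image, 3), dim = c(shape, 3))
  if (alpha > 0) {
    idx <- which(!is.na(field))
    cols <- ramp(field[idx]) # n x 3, 0-255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- (1 - alpha) * plane[idx] + alpha * cols[, ch]
      out[, , ch] <- plane
    }
  }
  out
}
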