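# Grayscale conversion, sliding-window tile grids, mask-area fractions and
# the tile-inclusion filters.

#' Convert an image to grayscale
#'
#' Single-channel input passes through unchanged; 3-channel input is
#' reduced with luminance weights (Rec.601 by default).
#'
#' @param image Numeric matrix (grayscale) or `rows x cols x 3` array.
#' @param weights Length-3 luminance coefficients; normalised to sum 1.
#' @return Numeric matrix.
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3) {
    w <- weights / sum(weights)
    return(image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3])
  }
  stop_invalid("unsupported channel count; expected 1 or 3 channels")
}

#' Extract a sliding-window tile grid
#'
#' Tiles are `size x size` half-open windows `[row0, row0 + size)` anchored
#' at 0-based positions on a regular stride, enumerated row-major. Boundary
#' remainder pixels that do not fit a full window are dropped.
#'
#' @param image Grayscale matrix, or an integer `c(rows, cols)` extent.
#' @param size Tile side in pixels (default 512).
#' @param stride Step between tile anchors in pixels (default 256).
#' @return A data frame of class `tile_grid` with columns `tile_id`,
#'   `grid_row`, `grid_col`, `row0`, `col0` and attributes `size`, `stride`,
#'   `image_shape`, `grid_dim`. Images smaller than `size` in either axis
#'   give an empty grid.
#' @export
extract_grid <- function(image, size = 512L, stride = 256L) {
  if (size <= 0 || stride <= 0) stop_invalid("size and stride must be > 0")
  size <- as.integer(size)
  stride <- as.integer(stride)
  shape <- if (is.matrix(image)) dim(image) else as.integer(image)
  n_r <- if (shape[1] >= size) (shape[1] - size) %/% stride + 1L else 0L
  n_c <- if (shape[2] >= size) (shape[2] - size) %/% stride + 1L else 0L
  if (n_r == 0L || n_c == 0L) {
    grid <- data.frame(tile_id = character(0), grid_row = integer(0),
                       grid_col = integer(0), row0 = integer(0),
                       col0 = integer(0))
    n_r <- n_c <- 0L
  } else {
    gr <- rep(seq_len(n_r) - 1L, each = n_c)
    gc <- rep(seq_len(n_c) - 1L, times = n_r)
    grid <- data.frame(
      tile_id = sprintf("t%04d_%04d", gr, gc),
      grid_row = gr, grid_col = gc,
      row0 = gr * as.integer(stride), col0 = gc * as.integer(stride))
  }
  structure(grid, size = as.integer(size), stride = as.integer(stride),
            image_shape = shape, grid_dim = c(n_r, n_c),
            class = c("tile_grid", "data.frame"))
}

#' Apply the tile-inclusion filters
#'
#' Computes fat / bone / vessel area fractions per tile and flags a tile as
#' included when fat < 50%, bone < 1% and vessel < 10% of the tile area
#' (strict inequalities). An optional analyzable-tissue mask additionally
#' requires more than half the tile to be analyzable.
#'
#' @param grid A `tile_grid`.
#' @param layout List with logical `fat_mask`, `bone_mask`, `vessel_mask`
#'   matrices matching the grid's image shape.
#' @param thresholds Named vector of strict upper bounds for the fractions.
#' @param analyzable_mask Optional logical matrix restricting the grid.
#' @return The grid with `fat_frac`, `bone_frac`, `vessel_frac` and
#'   `included` columns.
#' @export
apply_filters <- function(grid, layout,
                          thresholds = c(fat = 0.50, bone = 0.01,
                                         vessel = 0.10),
                          analyzable_mask = NULL) {
  shape <- attr(grid, "image_shape")
  size <- attr(grid, "size")
  for (m in c("fat_mask", "bone_mask", "vessel_mask")) {
    if (!all(dim(layout[[m]]) == shape)) {
      stop_invalid(m, " shape does not match the grid's image shape")
    }
  }
  if (nrow(grid) == 0) {
    grid$fat_frac <- grid$bone_frac <- grid$vessel_frac <- numeric(0)
    grid$included <- logical(0)
    return(grid)
  }
  area <- as.numeric(size)^2
  frac <- function(mask) {
    window_sums(integral_image(mask * 1), grid$row0, grid$col0, size) / area
  }
  grid$fat_frac <- frac(layout$fat_mask)
  grid$bone_frac <- frac(layout$bone_mask)
  grid$vessel_frac <- frac(layout$vessel_mask)
  grid$included <- grid$fat_frac < thresholds[["fat"]] &
    grid$bone_frac < thresholds[["bone"]] &
    grid$vessel_frac < thresholds[["vessel"]]
  if (!is.null(analyzable_mask)) {
    if (!all(dim(analyzable_mask) == shape)) {
      stop_invalid("analyzable_mask shape does not match the image shape")
    }
    an <- frac(analyzable_mask)
    grid$included <- grid$included & an > 0.5
  }
  grid
}
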