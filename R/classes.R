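# Lightweight S3 containers shared across modules.
#
# Coordinate convention, used everywhere: continuous millimetre
# coordinates with the origin at the top-left cell center, 0-based, and
# (row, col) = (y, x) ordering in arrays; landmark tables carry (x, y)
# columns in mm.

#' Probability map container
#'
#' Per-pixel classifier probabilities in \[0,1\] at micrometre pitch.
#'
#' @param grid numeric matrix of probabilities (NA allowed for missing)
#' @param pixel_size_um micrometres per pixel
#' @return object of class `probability_map`
#' @export
new_probability_map <- function(grid, pixel_size_um) {
  stopifnot(is.matrix(grid))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  v <- grid[!is.na(grid)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("probability values must lie in [0, 1]")
  structure(list(grid = grid, pixel_size_um = pixel_size_um),
            class = "probability_map")
}

#' Binary mask container
#'
#' @param grid 0/1 matrix
#' @param pixel_size_um micrometres per pixel
#' @param threshold_used probability threshold that produced the mask
#'   (NA if the mask did not come from thresholding)
#' @return object of class `binary_mask`
#' @export
new_binary_mask <- function(grid, pixel_size_um, threshold_used = NA_real_) {
  stopifnot(is.matrix(grid))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (!is_binary_values(grid)) stop("mask values must be 0 or 1")
  if (!is.na(threshold_used) && (threshold_used < 0 || threshold_used > 1))
    stop("threshold_used must be in [0, 1]")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 threshold_used = threshold_used),
            class = "binary_mask")
}

#' 3D volume container
#'
#' Array layout is (row, col, slice) with per-axis spacing in mm; this
#' package's stated axis-order convention for all volumes.
#'
#' @param grid 3D numeric array (a matrix is promoted to one slice)
#' @param spacing per-axis spacing in mm (length 1 or 3)
#' @param origin mm coordinate of the first voxel center
#' @return object of class `volume3d`
#' @export
new_volume3d <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(grid)) grid <- array(grid, dim = c(dim(grid), 1L))
  stopifnot(length(dim(grid)) == 3L)
  spacing <- rep(spacing, length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be positive on every axis")
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.phantom_label_map <- function(x, ...) {
  cat("<phantom_label_map> ", paste(dim(x$grid), collapse = " x "),
      " cells @ ", x$spacing_mm, " mm\n", sep = "")
  tab <- table(factor(x$grid, levels = x$labels, labels = names(x$labels)))
  print(tab)
  invisible(x)
}

#' @export
print.burden_heatmap <- function(x, ...) {
  cat("<burden_heatmap> ", paste(dim(x$grid), collapse = " x "),
      " cells @ ", x$spacing_mm, " mm; ",
      sum(x$valid_mask), " valid cells\n", sep = "")
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}
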