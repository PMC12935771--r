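#' Landmark-based registration
#'
#' 2D thin-plate-spline (TPS) registration of stained sections to their
#' blockface photographs, application of fitted transforms to
#' quantitative heatmaps by inverse mapping, stacking of sections into a
#' 3D volume, least-squares 3D affine alignment, and Dice-coefficient
#' registration QC.
#'
#' @name histo_registration
NULL

as_landmarks <- function(landmarks) {
  if (is.matrix(landmarks)) landmarks <- as.data.frame(landmarks)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(landmarks)))
    stop("landmarks need columns ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(landmarks[need]))))
    stop("landmark coordinates must be finite")
  landmarks
}

#' Swap the source and destination sides of a landmark table
#'
#' Used to fit the backward (output-to-source) transform needed for
#' inverse-mapping resampling.
#'
#' @param landmarks data.frame with src_x, src_y, dst_x, dst_y
#' @return the same table with the two sides exchanged
#' @export
swap_landmarks <- function(landmarks) {
  l <- as_landmarks(landmarks)
  data.frame(src_x = l$dst_x, src_y = l$dst_y,
             dst_x = l$src_x, dst_y = l$src_y)
}

tps_kernel <- function(r) {
  u <- r^2 * log(r)
  u[r == 0] <- 0
  u
}

#' Fit a 2D thin-plate-spline transform to paired landmarks
#'
#' Solves the standard TPS system with kernel U(r) = r^2 log r: an
#' affine part plus radial coefficients satisfying the side conditions
#' (zero sum and zero first moment). With `lambda = 0` the transform
#' interpolates every landmark exactly; `lambda > 0` trades
#' interpolation for smoothness, appropriate for jittered landmarks.
#'
#' @param landmarks data.frame with columns src_x, src_y, dst_x, dst_y
#'   (mm); at least 3 non-collinear source points
#' @param lambda regularization, >= 0
#' @return object of class `tps_transform`
#' @export
fit_tps <- function(landmarks, lambda = 0) {
  l <- as_landmarks(landmarks)
  n <- nrow(l)
  if (n < 3) stop("need at least 3 landmark pairs for a 2D TPS")
  if (lambda < 0) stop("lambda must be >= 0")
  src <- cbind(l$src_x, l$src_y)
  dst <- cbind(l$dst_x, l$dst_y)
  if (lambda == 0 && anyDuplicated(src))
    stop("duplicate source landmarks with lambda = 0 make the system singular")
  ctr <- scale(src, center = TRUE, scale = FALSE)
  sv <- svd(ctr)$d
  if (length(sv) < 2 || sv[2] < 1e-9 * max(sv[1], 1))
    stop("collinear source landmarks: TPS system is singular")

  D <- as.matrix(stats::dist(src))
  K <- tps_kernel(D)
  P <- cbind(1, src)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- solve(L, rhs)
  structure(list(w = sol[seq_len(n), , drop = FALSE],
                 a = sol[n + 1:3, , drop = FALSE],
                 src = src, lambda = lambda),
            class = "tps_transform")
}

#' Evaluate a TPS transform at points
#'
#' @param transform a `tps_transform`
#' @param points n x 2 matrix or data.frame of (x, y) in mm
#' @return n x 2 matrix of mapped (x, y)
#' @export
tps_apply <- function(transform, points) {
  stopifnot(inherits(transform, "tps_transform"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must be n x 2 (x, y)")
  D <- sqrt(outer(pts[, 1], transform$src[, 1], `-`)^2 +
            outer(pts[, 2], transform$src[, 2], `-`)^2)
  out <- cbind(1, pts) %*% transform$a + tps_kernel(D) %*% transform$w
  colnames(out) <- c("x", "y")
  out
}

#' Resample an image or heatmap under a fitted transform
#'
#' Inverse mapping: for each output cell center, `transform` is
#' evaluated to obtain the source-space sampling location, so `transform`
#' must map output-space coordinates to source-space coordinates (fit it
#' on swapped landmarks via [swap_landmarks()] when registering a
#' section into blockface space). Cells mapping outside the source are
#' marked invalid. Fractional heatmaps default to linear interpolation;
#' use nearest for masks.
#'
#' @param image numeric matrix or `burden_heatmap`
#' @param transform a `tps_transform` mapping output mm coords to source
#'   mm coords
#' @param out_shape output grid dimension (rows, cols)
#' @param out_spacing_mm output cell size, mm
#' @param in_spacing_mm source cell size, mm (taken from a heatmap input)
#' @param interpolation `"linear"` or `"nearest"`
#' @return same flavor as the input: a matrix with NA outside, or a
#'   `burden_heatmap` with an updated valid mask
#' @export
apply_transform_2d <- function(image, transform, out_shape, out_spacing_mm,
                               in_spacing_mm = NULL,
                               interpolation = c("linear", "nearest")) {
  if (!interpolation[1] %in% c("linear", "nearest"))
    stop("unknown interpolation mode '", interpolation[1], "'")
  interpolation <- match.arg(interpolation)
  if (any(out_spacing_mm <= 0)) stop("output grid spacing must be positive")
  is_heatmap <- inherits(image, "burden_heatmap")
  grid <- if (is_heatmap) image$grid else image
  in_spacing_mm <- in_spacing_mm %||%
    (if (is_heatmap) image$spacing_mm else stop("in_spacing_mm required"))
  out_shape <- rep(out_shape, length.out = 2L)

  gy <- rep((seq_len(out_shape[1]) - 1) * out_spacing_mm,
            times = out_shape[2])
  gx <- rep((seq_len(out_shape[2]) - 1) * out_spacing_mm,
            each = out_shape[1])
  src <- tps_apply(transform, cbind(gx, gy))
  ry <- src[, "y"] / in_spacing_mm + 1
  rx <- src[, "x"] / in_spacing_mm + 1
  sample_fun <- if (interpolation == "linear") bilinear_sample else nearest_sample
  v <- sample_fun(grid, ry, rx)
  out <- matrix(v, out_shape[1], out_shape[2])
  if (!is_heatmap) return(out)

  vsamp <- nearest_sample(image$valid_mask * 1, ry, rx)
  valid <- matrix(!is.na(v) & !is.na(vsamp) & vsamp > 0.5,
                  out_shape[1], out_shape[2])
  out[!valid] <- NA_real_
  structure(list(grid = out, spacing_mm = out_spacing_mm, valid_mask = valid,
                 provenance = c(image$provenance,
                                list(registered = TRUE,
                                     interpolation = interpolation))),
            class = "burden_heatmap")
}

#' Stack ordered 2D sections into a 3D volume
#'
#' @param slices ordered list of equally shaped 2D matrices (or
#'   `burden_heatmap`s, whose grids are stacked)
#' @param slice_spacing_mm through-plane spacing, mm
#' @param in_plane_spacing_mm in-plane cell size, mm (taken from heatmap
#'   inputs when omitted)
#' @return a `volume3d` with grid dim (rows, cols, n_slices)
#' @export
stack_sections <- function(slices, slice_spacing_mm, in_plane_spacing_mm = NULL) {
  stopifnot(length(slices) >= 1L)
  if (slice_spacing_mm <= 0) stop("slice_spacing_mm must be positive")
  grids <- lapply(slices, function(s)
    if (inherits(s, "burden_heatmap")) s$grid else s)
  in_plane_spacing_mm <- in_plane_spacing_mm %||%
    (if (inherits(slices[[1]], "burden_heatmap")) slices[[1]]$spacing_mm else 1)
  ref <- dim(grids[[1]])
  for (k in seq_along(grids))
    if (!identical(dim(grids[[k]]), ref))
      stop("slice ", k, " has shape ", paste(dim(grids[[k]]), collapse = "x"),
           ", expected ", paste(ref, collapse = "x"))
  arr <- array(unlist(grids), dim = c(ref, length(grids)))
  new_volume3d(arr, c(in_plane_spacing_mm, in_plane_spacing_mm,
                      slice_spacing_mm))
}

#' Least-squares 12-parameter 3D affine from paired landmarks
#'
#' @param landmarks data.frame with columns src_x, src_y, src_z, dst_x,
#'   dst_y, dst_z; at least 4 non-coplanar source points
#' @return object of class `affine3d` with matrix `A` (3 x 3) and
#'   offset `b`
#' @export
fit_affine_3d <- function(landmarks) {
  l <- if (is.matrix(landmarks)) as.data.frame(landmarks) else landmarks
  need <- c("src_x", "src_y", "src_z", "dst_x", "dst_y", "dst_z")
  if (!all(need %in% names(l)))
    stop("landmarks need columns ", paste(need, collapse = ", "))
  if (nrow(l) < 4) stop("need at least 4 landmark pairs for a 3D affine")
  src <- as.matrix(l[c("src_x", "src_y", "src_z")])
  dst <- as.matrix(l[c("dst_x", "dst_y", "dst_z")])
  ctr <- scale(src, center = TRUE, scale = FALSE)
  sv <- svd(ctr)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("coplanar source landmarks: 3D affine is underdetermined")
  X <- cbind(1, src)
  beta <- stats::lm.fit(X, dst)$coefficients
  structure(list(A = t(beta[-1, , drop = FALSE]), b = as.numeric(beta[1, ])),
            class = "affine3d")
}

#' Apply a 3D affine to points
#'
#' @param transform an `affine3d`
#' @param points n x 3 matrix of (x, y, z)
#' @return n x 3 matrix of mapped points
#' @export
affine3d_apply <- function(transform, points) {
  stopifnot(inherits(transform, "affine3d"))
  pts <- as.matrix(points)
  sweep(pts %*% t(transform$A), 2, -transform$b)
}

#' Dice overlap coefficient with registration QC
#'
#' value = 2 |A intersect B| / (|A| + |B|). Two empty masks are defined
#' as perfectly overlapping (value 1) with a warning flag, a case real
#' registrations never hit.
#'
#' @param a,b binary masks (matrix/array of 0/1 or logical, or
#'   `binary_mask`) of identical shape
#' @param qc_bar pass bar for registration QC (default 0.8)
#' @return list: `value`, `qc_pass`, `empty_warning`
#' @export
dice_coefficient <- function(a, b, qc_bar = 0.8) {
  ga <- if (inherits(a, "binary_mask")) a$grid else a
  gb <- if (inherits(b, "binary_mask")) b$grid else b
  if (!identical(dim(ga), dim(gb))) stop("mask shape mismatch")
  if (!is_binary_values(ga) || !is_binary_values(gb))
    stop("inputs must be binary masks")
  ga <- !is.na(ga) & ga == 1
  gb <- !is.na(gb) & gb == 1
  sa <- sum(ga); sb <- sum(gb)
  if (sa + sb == 0) {
    warning("both masks empty: Dice defined as 1")
    return(list(value = 1, qc_pass = 1 >= qc_bar, empty_warning = TRUE))
  }
  v <- 2 * sum(ga & gb) / (sa + sb)
  list(value = v, qc_pass = v >= qc_bar, empty_warning = FALSE)
}
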