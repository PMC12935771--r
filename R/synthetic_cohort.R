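#' Synthetic cohort generators
#'
#' The functions in this file build a fully seeded synthetic "case": an
#' anatomical label map, per-marker positive-pixel masks at micrometre
#' pitch, noisy per-pixel probability maps (the stand-in for a CNN or
#' Weka classifier output), a smooth section-to-blockface warp with
#' paired landmarks, and a PET SUVR volume generated from a known linear
#' combination of smoothed burdens. Every generator is a pure function
#' of its parameters and seed.
#'
#' @name synthetic_cohort
NULL

REGION_LABELS <- c(background = 0L, cortex = 1L, white_matter = 2L,
                   lentiform = 3L, hippocampus = 4L)

MARKERS <- c("ptau", "iron", "maob")

#' Generate a 2D anatomical phantom label map
#'
#' Builds a hemisphere-like slab: an elliptical tissue region whose
#' boundary ribbon is cortex, an interior of white matter, and two
#' compact interior structures (lentiform nucleus and hippocampus).
#' Geometry is jittered deterministically by `seed`.
#'
#' @param shape cells per axis (length 1 or 2), at least 32 per axis
#' @param spacing_mm cell size in millimetres
#' @param seed integer seed
#' @return an object of class `phantom_label_map` with fields `grid`
#'   (integer matrix), `spacing_mm`, and `labels` (named legend)
#' @export
generate_label_map <- function(shape, spacing_mm = 1, seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 2L))
  if (any(shape < 32L))
    stop("grid too small to host the cortex ribbon and interior structures: ",
         "need >= 32 cells per axis")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    cy <- (nr + 1) / 2 * (1 + stats::runif(1, -0.02, 0.02))
    cx <- (nc + 1) / 2 * (1 + stats::runif(1, -0.02, 0.02))
    ay <- 0.45 * nr * (1 + stats::runif(1, -0.03, 0.03))
    ax <- 0.45 * nc * (1 + stats::runif(1, -0.03, 0.03))
    tissue <- ellipse_mask(shape, c(cy, cx), c(ay, ax))
    th <- max(2, round(0.08 * min(shape)))
    inner <- ellipse_mask(shape, c(cy, cx), c(ay - th, ax - th))
    grid <- matrix(0L, nr, nc)
    grid[tissue] <- REGION_LABELS[["cortex"]]
    grid[inner] <- REGION_LABELS[["white_matter"]]

    place_blob <- function(grid, frac_center, frac_semi, label, name) {
      ctr <- c(cy + frac_center[1] * nr + stats::runif(1, -0.03, 0.03) * nr,
               cx + frac_center[2] * nc + stats::runif(1, -0.03, 0.03) * nc)
      semi <- frac_semi * min(shape)
      blob <- ellipse_mask(shape, ctr, semi) & inner
      if (!any(blob))
        stop("grid too small to host region '", name, "'")
      grid[blob] <- label
      grid
    }
    grid <- place_blob(grid, c(-0.08, -0.14), c(0.07, 0.10),
                       REGION_LABELS[["lentiform"]], "lentiform")
    grid <- place_blob(grid, c(0.14, 0.10), c(0.06, 0.08),
                       REGION_LABELS[["hippocampus"]], "hippocampus")
    if (!all(REGION_LABELS %in% grid))
      stop("grid too small to host region '",
           names(REGION_LABELS)[!REGION_LABELS %in% grid][1], "'")
    structure(list(grid = grid, spacing_mm = spacing_mm,
                   labels = REGION_LABELS),
              class = "phantom_label_map")
  })
}

# expand a cell-level label grid to pixel resolution by index replication
label_grid_at_pixels <- function(label_map, pixel_size_um) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  ppc <- label_map$spacing_mm * 1000 / pixel_size_um
  if (ppc < 1) stop("pixel_size_um larger than a label-map cell")
  dims <- dim(label_map$grid)
  npr <- as.integer(round(dims[1] * ppc))
  npc <- as.integer(round(dims[2] * ppc))
  ri <- pmin(dims[1], floor((seq_len(npr) - 0.5) / ppc) + 1L)
  ci <- pmin(dims[2], floor((seq_len(npc) - 0.5) / ppc) + 1L)
  label_map$grid[ri, ci, drop = FALSE]
}

default_density_spec <- function(marker) {
  switch(marker,
    ptau = c(background = 0, cortex = 0.25, white_matter = 0.02,
             lentiform = 0.03, hippocampus = 0.35),
    iron = c(background = 0, cortex = 0.02, white_matter = 0.02,
             lentiform = 0.25, hippocampus = 0.03),
    maob = c(background = 0, cortex = 0.05, white_matter = 0.25,
             lentiform = 0.08, hippocampus = 0.05))
}

default_blob_spec <- function(marker) {
  # texture correlation lengths in micrometres: tangle-like clusters for
  # p-tau, hard hemosiderin puncta for iron, diffuse astrocytic texture
  # for MAO-B
  switch(marker,
    ptau = list(sigma_um = 100),
    iron = list(sigma_um = 15),
    maob = list(sigma_um = 300))
}

#' Generate a marker-positive pixel mask on a phantom
#'
#' Draws a marker-specific textured random field (blob clusters for
#' p-tau, puncta for ferric iron, diffuse texture for MAO-B) and
#' thresholds it within each anatomical region at the quantile that
#' realizes the requested per-region positive fraction, so the empirical
#' density matches `density_spec` up to the granularity of the region.
#'
#' @param label_map a `phantom_label_map`
#' @param marker one of `"ptau"`, `"iron"`, `"maob"`
#' @param pixel_size_um micrometres per histology pixel
#' @param density_spec named per-region positive fractions in \[0,1\];
#'   defaults are marker-specific
#' @param blob_spec list with `sigma_um`, the texture correlation length
#' @param seed integer seed
#' @return an object of class `marker_truth` with fields `marker`,
#'   `mask` (integer 0/1 matrix), `pixel_size_um`, `region_density`
#' @export
generate_marker_truth <- function(label_map, marker, pixel_size_um = 10,
                                  density_spec = NULL, blob_spec = NULL,
                                  seed = 1L) {
  if (!marker %in% MARKERS)
    stop("unknown marker '", marker, "'; expected one of: ",
         paste(MARKERS, collapse = ", "))
  density_spec <- density_spec %||% default_density_spec(marker)
  blob_spec <- blob_spec %||% default_blob_spec(marker)
  if (any(density_spec < 0 | density_spec > 1))
    stop("density_spec values must be in [0, 1]")
  labels_px <- label_grid_at_pixels(label_map, pixel_size_um)
  with_seed(seed, {
    n <- length(labels_px)
    field <- matrix(stats::rnorm(n), nrow(labels_px), ncol(labels_px))
    sigma_px <- blob_spec$sigma_um / pixel_size_um
    if (sigma_px >= 0.3) field <- sep_conv(field, sigma_px)
    mask <- matrix(0L, nrow(labels_px), ncol(labels_px))
    for (region in names(density_spec)) {
      lab <- label_map$labels[[region]]
      if (is.null(lab)) stop("unknown region '", region, "' in density_spec")
      sel <- labels_px == lab
      if (!any(sel)) next
      f <- density_spec[[region]]
      if (f <= 0) next
      if (f >= 1) { mask[sel] <- 1L; next }
      thr <- stats::quantile(field[sel], 1 - f, names = FALSE, type = 7)
      mask[sel] <- as.integer(field[sel] >= thr)
    }
    structure(list(marker = marker, mask = mask,
                   pixel_size_um = pixel_size_um,
                   region_density = density_spec),
              class = "marker_truth")
  })
}

check_beta_params <- function(p, what) {
  if (length(p) == 1L) {
    if (!is.finite(p) || p < 0 || p > 1)
      stop(what, ": a point-mass parameter must lie in [0, 1] ",
           "(mass outside [0, 1] is not a valid pixel probability)")
  } else if (length(p) == 2L) {
    if (any(!is.finite(p)) || any(p <= 0))
      stop(what, ": Beta shape parameters must be positive")
  } else stop(what, ": give either Beta shapes c(a, b) or a point mass")
  invisible(p)
}

#' Corrupt a ground-truth mask into a classifier-like probability map
#'
#' Emulates per-pixel classifier output: positive pixels draw their
#' probability from `pos_params`, background pixels from `neg_params`.
#' Parameters are Beta shape pairs `c(a, b)`, or a single number in
#' \[0,1\] for a degenerate point mass (the noiseless limit).
#'
#' @param truth a `marker_truth`
#' @param pos_params,neg_params Beta shapes or point mass for the
#'   positive and background classes
#' @param seed integer seed
#' @return a `probability_map`
#' @export
corrupt_to_probability <- function(truth, pos_params = c(5, 2),
                                   neg_params = c(2, 5), seed = 1L) {
  stopifnot(inherits(truth, "marker_truth"))
  check_beta_params(pos_params, "pos_params")
  check_beta_params(neg_params, "neg_params")
  m <- truth$mask
  with_seed(seed, {
    draw <- function(n, p) {
      if (n == 0L) return(numeric(0))
      if (length(p) == 1L) rep(as.numeric(p), n) else stats::rbeta(n, p[1], p[2])
    }
    pos <- m == 1L
    g <- matrix(NA_real_, nrow(m), ncol(m))
    g[pos] <- draw(sum(pos), pos_params)
    g[!pos] <- draw(sum(!pos), neg_params)
    new_probability_map(g, truth$pixel_size_um)
  })
}

#' Construct PET ground truth for the generative model
#'
#' Records the generative counterpart of the full regression model:
#' voxelwise SUVR = intercept + sum of per-marker coefficients times
#' burden, plus Gaussian noise, after the burdens have been smoothed to
#' the scanner point-spread FWHM.
#'
#' @param betas named coefficients; first element `intercept`, remaining
#'   names are markers (SUVR units per unit burden)
#' @param noise_sd Gaussian noise standard deviation, SUVR units
#' @param pet_fwhm_mm scanner point-spread FWHM in millimetres
#' @param seed integer seed for the noise draw
#' @return an object of class `pet_ground_truth`
#' @export
pet_ground_truth <- function(betas = c(intercept = 1.1, ptau = 0.7,
                                       iron = 0.4, maob = 0.0),
                             noise_sd = 0.1, pet_fwhm_mm = 5, seed = 1L) {
  if (is.null(names(betas)) || names(betas)[1] != "intercept")
    stop("betas must be named, with the first element 'intercept'")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pet_fwhm_mm <= 0) stop("pet_fwhm_mm must be positive")
  structure(list(betas = betas, noise_sd = noise_sd,
                 pet_fwhm_mm = pet_fwhm_mm, seed = seed),
            class = "pet_ground_truth")
}

#' Synthesize a PET SUVR volume from burden maps
#'
#' Voxelwise SUVR = intercept + sum over markers of beta times burden,
#' plus Gaussian noise of sd `gt$noise_sd` (seeded). The burdens are
#' taken as already living in PET space (i.e. smoothed to the scanner
#' FWHM); `synthesize_pet` only applies the linear model and noise.
#'
#' @param burdens named list of 3D arrays or `volume3d` objects, one per
#'   marker in `gt$betas`, all sharing shape and spacing
#' @param gt a `pet_ground_truth`
#' @return a `volume3d` SUVR volume with the ground truth attached as
#'   attribute `"ground_truth"`
#' @export
synthesize_pet <- function(burdens, gt) {
  stopifnot(inherits(gt, "pet_ground_truth"))
  markers <- names(gt$betas)[-1]
  grids <- lapply(burdens, function(b) if (inherits(b, "volume3d")) b$grid else b)
  spacing <- if (inherits(burdens[[1]], "volume3d")) burdens[[1]]$spacing else c(1, 1, 1)
  dims <- lapply(grids, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("shape mismatch between burden grids")
  ref_dim <- dims[[1]]
  suvr <- array(gt$betas[["intercept"]], dim = ref_dim)
  for (m in markers) {
    if (gt$betas[[m]] == 0) next
    if (is.null(grids[[m]]))
      stop("burden grid missing for marker '", m, "' with nonzero beta")
    suvr <- suvr + gt$betas[[m]] * grids[[m]]
  }
  if (gt$noise_sd > 0) {
    noise <- with_seed(gt$seed, stats::rnorm(length(suvr), 0, gt$noise_sd))
    suvr <- suvr + array(noise, dim = ref_dim)
  }
  out <- new_volume3d(suvr, spacing)
  attr(out, "ground_truth") <- gt
  out
}

#' Define a random smooth 2D warp
#'
#' A sum of Gaussian radial-basis displacement bumps at seeded control
#' points, emulating the smooth tissue distortion introduced by
#' immunohistochemistry processing of a section relative to its
#' blockface photograph.
#'
#' @param extent_mm field of view, mm (length 2: rows, cols)
#' @param n_control number of displacement control points
#' @param max_disp_mm approximate maximum displacement magnitude, mm
#' @param scale_mm RBF length scale, mm (default a quarter of the extent)
#' @param landmark_jitter_sd landmark measurement noise sd, mm
#' @param seed integer seed
#' @return an object of class `warp_ground_truth`
#' @export
random_smooth_warp <- function(extent_mm, n_control = 6, max_disp_mm = 1.5,
                               scale_mm = NULL, landmark_jitter_sd = 0.1,
                               seed = 1L) {
  extent_mm <- rep(extent_mm, length.out = 2L)
  scale_mm <- scale_mm %||% (min(extent_mm) / 4)
  with_seed(seed, {
    ctr <- cbind(x = stats::runif(n_control, 0.15, 0.85) * extent_mm[2],
                 y = stats::runif(n_control, 0.15, 0.85) * extent_mm[1])
    d <- cbind(dx = stats::runif(n_control, -1, 1),
               dy = stats::runif(n_control, -1, 1))
    mag <- sqrt(rowSums(d^2))
    d <- d / pmax(mag, 1e-12) * stats::runif(n_control, 0.3, 1) * max_disp_mm
    structure(list(control = cbind(ctr, d), scale_mm = scale_mm,
                   extent_mm = extent_mm,
                   landmark_jitter_sd = landmark_jitter_sd),
              class = "warp_ground_truth")
  })
}

#' Identity / pure-translation warp
#'
#' @param extent_mm field of view, mm
#' @param shift_mm translation `c(dx, dy)` in mm
#' @param landmark_jitter_sd landmark noise sd, mm
#' @return a `warp_ground_truth`
#' @export
translation_warp <- function(extent_mm, shift_mm = c(0, 0),
                             landmark_jitter_sd = 0) {
  extent_mm <- rep(extent_mm, length.out = 2L)
  ctrl <- cbind(x = extent_mm[2] / 2, y = extent_mm[1] / 2,
                dx = shift_mm[1], dy = shift_mm[2])
  structure(list(control = ctrl, scale_mm = Inf, extent_mm = extent_mm,
                 landmark_jitter_sd = landmark_jitter_sd),
            class = "warp_ground_truth")
}

# evaluate the warp psi(p) = p + displacement at points (x, y) in mm
warp_eval <- function(warp, x, y) {
  dx <- numeric(length(x)); dy <- numeric(length(y))
  ctrl <- warp$control
  for (k in seq_len(nrow(ctrl))) {
    if (is.infinite(warp$scale_mm)) {
      w <- 1
    } else {
      w <- exp(-((x - ctrl[k, "x"])^2 + (y - ctrl[k, "y"])^2) /
                 (2 * warp$scale_mm^2))
    }
    dx <- dx + w * ctrl[k, "dx"]
    dy <- dy + w * ctrl[k, "dy"]
  }
  cbind(x = x + dx, y = y + dy)
}

#' Resample an image under a known smooth warp
#'
#' Produces the "section" image: pixel p of the output takes the value of
#' the input ("blockface") image at psi(p) = p + displacement(p),
#' sampled bilinearly. Coordinates are mm, origin at the top-left pixel
#' center.
#'
#' @param image numeric matrix (the reference-space image)
#' @param warp a `warp_ground_truth`
#' @param spacing_mm pixel pitch of `image`, mm
#' @param interpolation `"linear"` or `"nearest"`
#' @return warped matrix of the same shape (regions mapping outside the
#'   input are 0)
#' @export
warp_image <- function(image, warp, spacing_mm, interpolation = "linear") {
  nr <- nrow(image); nc <- ncol(image)
  xs <- (seq_len(nc) - 1) * spacing_mm
  ys <- (seq_len(nr) - 1) * spacing_mm
  gx <- rep(xs, each = nr)
  gy <- rep(ys, times = nc)
  src <- warp_eval(warp, gx, gy)
  ry <- src[, "y"] / spacing_mm + 1
  rx <- src[, "x"] / spacing_mm + 1
  v <- switch(interpolation,
              linear = bilinear_sample(image, ry, rx),
              nearest = nearest_sample(image, ry, rx),
              stop("unknown interpolation mode '", interpolation, "'"))
  v[is.na(v)] <- 0
  matrix(v, nr, nc)
}

#' Generate noisy landmark pairs under a known warp
#'
#' Samples landmark positions in the section (output) space -- spread
#' over a jittered grid, the way an annotator distributes landmarks over
#' the tissue rather than placing them uniformly at random -- and pairs
#' them with their true blockface correspondences psi(p), plus Gaussian
#' jitter of sd `warp$landmark_jitter_sd` on the blockface side.
#'
#' @param warp a `warp_ground_truth`
#' @param n number of landmarks
#' @param seed integer seed
#' @return data.frame with columns `src_x, src_y, dst_x, dst_y` (mm);
#'   `src` is section space, `dst` is blockface space
#' @export
warp_landmark_pairs <- function(warp, n = 12, seed = 1L) {
  with_seed(seed, {
    g <- ceiling(sqrt(n))
    cell <- 0.8 / g
    centers <- 0.1 + cell * (expand.grid(gx = seq_len(g), gy = seq_len(g)) - 0.5)
    pick <- sample.int(g * g, n)
    sx <- (centers$gx[pick] + stats::runif(n, -0.35, 0.35) * cell) *
      warp$extent_mm[2]
    sy <- (centers$gy[pick] + stats::runif(n, -0.35, 0.35) * cell) *
      warp$extent_mm[1]
    dst <- warp_eval(warp, sx, sy)
    if (warp$landmark_jitter_sd > 0) {
      dst[, "x"] <- dst[, "x"] + stats::rnorm(n, 0, warp$landmark_jitter_sd)
      dst[, "y"] <- dst[, "y"] + stats::rnorm(n, 0, warp$landmark_jitter_sd)
    }
    out <- which(dst[, "x"] < 0 | dst[, "x"] > warp$extent_mm[2] |
                 dst[, "y"] < 0 | dst[, "y"] > warp$extent_mm[1])
    if (length(out))
      stop("landmarks fall outside the image after warping: ",
           paste(out, collapse = ", "))
    data.frame(src_x = sx, src_y = sy, dst_x = dst[, "x"], dst_y = dst[, "y"])
  })
}

#' Warp an image and return it with paired landmarks
#'
#' Convenience composition of [warp_image()] and [warp_landmark_pairs()]:
#' emulates a distorted stained section together with the landmark
#' correspondences an annotator would supply for registration.
#'
#' @inheritParams warp_image
#' @param n_landmarks number of landmark pairs
#' @param seed integer seed (landmark placement and jitter)
#' @return list with elements `warped` (matrix) and `landmarks`
#'   (data.frame as in [warp_landmark_pairs()])
#' @export
warp_with_landmarks <- function(image, warp, spacing_mm, n_landmarks = 12,
                                seed = 1L, interpolation = "linear") {
  fov <- c(ncol(image), nrow(image)) * spacing_mm
  probe <- warp_landmark_free_displacement(warp)
  if (probe >= 0.1 * min(fov))
    stop("warp displacements too large: max |d| = ", signif(probe, 3),
         " mm exceeds 10% of the field of view")
  list(warped = warp_image(image, warp, spacing_mm, interpolation),
       landmarks = warp_landmark_pairs(warp, n_landmarks, seed))
}

# conservative bound on the maximum displacement magnitude
warp_landmark_free_displacement <- function(warp) {
  ctrl <- warp$control
  gx <- seq(0, warp$extent_mm[2], length.out = 25)
  gy <- seq(0, warp$extent_mm[1], length.out = 25)
  g <- expand.grid(x = gx, y = gy)
  p <- warp_eval(warp, g$x, g$y)
  max(sqrt((p[, "x"] - g$x)^2 + (p[, "y"] - g$y)^2))
}
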