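#' Burden heatmaps and resolution matching
#'
#' Converts binary positive-pixel masks into quantitative percent-positive
#' heatmaps on a metric grid, estimates the effective spatial smoothness
#' (FWHM) of a field from its first-difference variance ratio, and
#' smooths fields iteratively until their estimated FWHM matches a
#' target -- the resolution-matching step between histology heatmaps and
#' PET.
#'
#' @name burden_heatmap
NULL

#' Percent-positive burden heatmap
#'
#' Tiles the mask into square cells of `tile_mm`, anchored at the image's
#' top-left corner (pixels are assigned to the tile containing their
#' center), and computes the fraction of positive pixels per tile. Edge
#' tiles holding fewer than `min_coverage` of a full tile's pixel budget
#' are marked invalid rather than silently diluting fractions.
#'
#' @param mask a `binary_mask`
#' @param tile_mm target cell size in millimetres (>= pixel pitch)
#' @param min_coverage minimum fraction of a full tile's expected pixel
#'   count for a cell to be valid, in (0, 1]
#' @return object of class `burden_heatmap`: fields `grid` (fractions,
#'   NA where no pixels), `spacing_mm`, `valid_mask`, `provenance`
#' @export
percent_positive_heatmap <- function(mask, tile_mm = 1, min_coverage = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  pitch_mm <- mask$pixel_size_um / 1000
  if (tile_mm < pitch_mm) stop("tile smaller than one pixel")
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  npr <- nrow(mask$grid); npc <- ncol(mask$grid)
  tr <- floor((seq_len(npr) - 0.5) * pitch_mm / tile_mm) + 1L
  tc <- floor((seq_len(npc) - 0.5) * pitch_mm / tile_mm) + 1L
  ntr <- max(tr); ntc <- max(tc)
  idx <- tr[row(mask$grid)] + (tc[col(mask$grid)] - 1L) * ntr
  nb <- ntr * ntc
  total <- tabulate(idx, nbins = nb)
  pos <- tabulate(idx[mask$grid == 1L], nbins = nb)
  full_tile <- (tile_mm / pitch_mm)^2
  grid <- matrix(ifelse(total > 0, pos / total, NA_real_), ntr, ntc)
  valid <- matrix(total / full_tile >= min_coverage & total > 0, ntr, ntc)
  structure(list(grid = grid, spacing_mm = tile_mm, valid_mask = valid,
                 provenance = list(tile_mm = tile_mm,
                                   min_coverage = min_coverage,
                                   pixel_size_um = mask$pixel_size_um,
                                   threshold_used = mask$threshold_used)),
            class = "burden_heatmap")
}

#' Estimate the spatial smoothness (FWHM) of a field
#'
#' Per-axis FWHM of the effective Gaussian smoothing kernel of a
#' stationary random field, from the variance ratio of first
#' differences: with s^2 the field variance and d^2 the variance of
#' first differences along an axis,
#' FWHM = spacing * sqrt(-2 ln 2 / ln(1 - d^2 / (2 s^2))).
#' Axes where d^2 >= 2 s^2 (no detectable smoothness, e.g. white noise)
#' are marked inestimable (NA).
#'
#' @param field 2D matrix or 3D array
#' @param spacing_mm per-axis spacing (recycled)
#' @param mask optional logical array of valid cells; differences use
#'   only neighbor pairs that are both valid
#' @return object of class `smoothness_estimate`: `fwhm_mm` per axis
#'   (NA = inestimable) and a method tag
#' @export
estimate_fwhm <- function(field, spacing_mm = 1, mask = NULL) {
  d <- dim(field)
  ndim <- length(d)
  stopifnot(ndim %in% c(2L, 3L))
  spacing_mm <- rep(spacing_mm, length.out = ndim)
  if (is.null(mask)) mask <- !is.na(field) else mask <- mask & !is.na(field)
  vals <- field[mask]
  if (length(vals) < 100) stop("need at least 100 valid cells")
  s2 <- stats::var(vals)
  if (!is.finite(s2) || s2 < .Machine$double.eps * max(abs(vals), 1))
    stop("constant field: zero variance, smoothness undefined")

  axis_fwhm <- function(axis) {
    shift <- function(a, k) {
      idx <- lapply(d, seq_len)
      idx[[axis]] <- seq_len(d[axis] - 1L) + k
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    x1 <- shift(field, 0L); x2 <- shift(field, 1L)
    m1 <- shift(mask, 0L); m2 <- shift(mask, 1L)
    ok <- m1 & m2
    dv <- (x2 - x1)[ok]
    if (length(dv) < 50) return(NA_real_)
    d2 <- stats::var(dv)
    ratio <- d2 / (2 * s2)
    if (!is.finite(ratio) || ratio >= 1) return(NA_real_)
    spacing_mm[axis] * sqrt(-2 * log(2) / log(1 - ratio))
  }
  fwhm <- vapply(seq_len(ndim), axis_fwhm, numeric(1))
  structure(list(fwhm_mm = fwhm, method = "first-difference variance ratio"),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("<smoothness_estimate> FWHM (mm):",
      paste(signif(x$fwhm_mm, 4), collapse = ", "),
      " [", x$method, "]\n", sep = "")
  invisible(x)
}

mean_fwhm <- function(est) {
  f <- est$fwhm_mm[!is.na(est$fwhm_mm)]
  if (!length(f)) return(0)  # inestimable on all axes = unsmoothed
  mean(f)
}

#' Smooth a field until its estimated FWHM matches a target
#'
#' Applies incremental isotropic Gaussian convolutions, starting from a
#' kernel of FWHM sqrt(target^2 - current^2) (Gaussian composition
#' identity) and refining against the post-hoc [estimate_fwhm()] of the
#' result. On overshoot the candidate step is rejected and the
#' incremental kernel width halved. A field whose smoothness is
#' inestimable (e.g. white noise) is treated as unsmoothed.
#'
#' @param field 2D matrix
#' @param spacing_mm cell size, mm (isotropic in-plane)
#' @param target_fwhm_mm target FWHM, mm; must be at least the current
#'   estimate (smoothing cannot sharpen)
#' @param tolerance relative tolerance on the matched FWHM (default 2%)
#' @param max_iter maximum refinement iterations
#' @param mask optional valid-cell mask (renormalized-kernel smoothing)
#' @return list: `field` (smoothed), `estimate` (a
#'   `smoothness_estimate`), `converged`, `iterations`, `warning`
#' @export
blur_to_fwhm <- function(field, spacing_mm = 1, target_fwhm_mm,
                         tolerance = 0.02, max_iter = 25, mask = NULL) {
  stopifnot(is.matrix(field))
  if (target_fwhm_mm <= 0) stop("target_fwhm_mm must be positive")
  est <- estimate_fwhm(field, spacing_mm, mask)
  cur <- mean_fwhm(est)
  if (cur > target_fwhm_mm * (1 + tolerance))
    stop("target FWHM (", target_fwhm_mm, " mm) is below the current estimate (",
         signif(cur, 4), " mm): smoothing cannot sharpen")
  if (abs(cur - target_fwhm_mm) <= tolerance * target_fwhm_mm)
    return(list(field = field, estimate = est, converged = TRUE,
                iterations = 0L, warning = FALSE))

  damp <- 1
  it <- 0L
  repeat {
    it <- it + 1L
    w <- sqrt(max(target_fwhm_mm^2 - cur^2, 0)) * damp
    sigma_px <- fwhm_to_sigma(w) / spacing_mm
    if (sigma_px < 0.2) {
      # increment below grid resolution: cannot move the estimate further
      return(list(field = field, estimate = est,
                  converged = abs(cur - target_fwhm_mm) <=
                    tolerance * target_fwhm_mm,
                  iterations = it, warning = TRUE))
    }
    cand <- smooth_2d(field, sigma_px, mask)
    cest <- estimate_fwhm(cand, spacing_mm, mask)
    cnew <- mean_fwhm(cest)
    if (cnew <= target_fwhm_mm * (1 + tolerance)) {
      field <- cand; est <- cest; cur <- cnew
      if (abs(cur - target_fwhm_mm) <= tolerance * target_fwhm_mm)
        return(list(field = field, estimate = est, converged = TRUE,
                    iterations = it, warning = FALSE))
    } else {
      damp <- damp / 2
    }
    if (it >= max_iter)
      return(list(field = field, estimate = est, converged = FALSE,
                  iterations = it, warning = TRUE))
  }
}

# interval-overlap matrix: rows = output cells, cols = input cells;
# entry = overlap length (mm) between output cell k and input cell i
overlap_matrix <- function(n_in, sp_in, sp_out) {
  n_out <- ceiling(n_in * sp_in / sp_out - 1e-9)
  A <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out)) {
    lo <- (k - 1) * sp_out; hi <- k * sp_out
    i0 <- max(1L, floor(lo / sp_in) + 1L)
    i1 <- min(n_in, ceiling(hi / sp_in))
    for (i in i0:i1)
      A[k, i] <- max(0, min(hi, i * sp_in) - max(lo, (i - 1) * sp_in))
  }
  A
}

#' Resample a burden heatmap to a coarser grid
#'
#' `mean` mode computes area-weighted averages of valid source cells via
#' exact interval-overlap weights, so the area-weighted global mean over
#' the valid region is conserved; `linear` mode samples bilinearly at
#' output cell centers. Upsampling is refused.
#'
#' @param h a `burden_heatmap`
#' @param target_spacing_mm output cell size (>= source spacing)
#' @param mode `"mean"` or `"linear"`
#' @param min_coverage minimum valid-area fraction for an output cell
#' @return a `burden_heatmap` at the target spacing, with the valid-area
#'   weights attached as attribute `"coverage"` (mean mode)
#' @export
resample_heatmap <- function(h, target_spacing_mm, mode = c("mean", "linear"),
                             min_coverage = 0.5) {
  stopifnot(inherits(h, "burden_heatmap"))
  mode <- match.arg(mode)
  sp <- h$spacing_mm
  if (target_spacing_mm < sp)
    stop("upsampling request: target spacing must be >= source spacing")
  V <- h$valid_mask & !is.na(h$grid)
  X <- h$grid; X[!V] <- 0
  if (mode == "mean") {
    A <- overlap_matrix(nrow(h$grid), sp, target_spacing_mm)
    B <- overlap_matrix(ncol(h$grid), sp, target_spacing_mm)
    W <- A %*% (V * 1) %*% t(B)            # valid source area per output cell
    S <- A %*% X %*% t(B)
    grid <- ifelse(W > 1e-12, S / W, NA_real_)
    valid <- W / target_spacing_mm^2 >= min_coverage
    out <- structure(list(grid = grid, spacing_mm = target_spacing_mm,
                          valid_mask = valid,
                          provenance = c(h$provenance,
                                         list(resampled_from_mm = sp,
                                              mode = "mean"))),
                     class = "burden_heatmap")
    attr(out, "coverage") <- W
    out
  } else {
    n_out_r <- ceiling(nrow(h$grid) * sp / target_spacing_mm - 1e-9)
    n_out_c <- ceiling(ncol(h$grid) * sp / target_spacing_mm - 1e-9)
    gy <- rep((seq_len(n_out_r) - 1) * target_spacing_mm, times = n_out_c)
    gx <- rep((seq_len(n_out_c) - 1) * target_spacing_mm, each = n_out_r)
    src <- h$grid; src[!V] <- NA
    v <- bilinear_sample(src, gy / sp + 1, gx / sp + 1)
    grid <- matrix(v, n_out_r, n_out_c)
    structure(list(grid = grid, spacing_mm = target_spacing_mm,
                   valid_mask = !is.na(grid),
                   provenance = c(h$provenance,
                                  list(resampled_from_mm = sp,
                                       mode = "linear"))),
              class = "burden_heatmap")
  }
}
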