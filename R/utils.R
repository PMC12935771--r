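#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so every generator in the package is a pure
#' function of its arguments and seed without touching global state.
#'
#' @param seed single integer-valued number
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Deterministic 31-bit mixing so pipeline stages can be re-run in
#' isolation with reproducible, mutually distinct streams.
#'
#' @param seed master seed
#' @param stage integer stage index
#' @return an integer in \[1, 2^31 - 2\]
#' @export
sub_seed <- function(seed, stage) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(stage) * 7919 + 1
  as.integer(s %% (m - 1) + 1)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# convolve each column of x with kernel k, zero-padded edges
conv_axis1 <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(x)
  n <- nrow(x)
  pad <- matrix(0, r, ncol(x))
  xp <- rbind(pad, x, pad)
  f <- stats::filter(xp, k, method = "convolution", sides = 2)
  matrix(f[(r + 1L):(r + n), ], nrow = n)
}

sep_conv <- function(x, sigma) {
  sigma <- rep(sigma, length.out = 2L)
  if (sigma[1] > 0) x <- conv_axis1(x, gauss_kernel(sigma[1]))
  if (sigma[2] > 0) x <- t(conv_axis1(t(x), gauss_kernel(sigma[2])))
  x
}

#' Gaussian smoothing with renormalized kernels over valid cells
#'
#' Separable 2D Gaussian convolution. Cells outside `mask` (or NA) do not
#' contribute, and the kernel is renormalized over the contributing
#' weight so values in \[0,1\] stay in \[0,1\] near edges and holes.
#'
#' @param x numeric matrix
#' @param sigma kernel standard deviation in cell units (scalar or per-axis)
#' @param mask optional logical matrix of valid cells
#' @return smoothed matrix; cells outside `mask` are NA
#' @export
smooth_2d <- function(x, sigma, mask = NULL) {
  stopifnot(is.matrix(x))
  sigma <- rep(sigma, length.out = 2L)
  if (all(sigma <= 0)) return(x)
  if (is.null(mask)) mask <- !is.na(x) else mask <- mask & !is.na(x)
  x0 <- x
  x0[!mask] <- 0
  num <- sep_conv(x0, sigma)
  den <- sep_conv(mask * 1, sigma)
  out <- num / den
  out[den < 1e-12] <- NA_real_
  out[!mask] <- NA_real_
  out
}

# bilinear sampling at continuous (row, col) positions, 1-based pixel units
bilinear_sample <- function(img, ry, rx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(ry))
  tol <- 1e-6  # tolerate rounding at the exact boundary
  ok <- is.finite(ry) & is.finite(rx) &
    ry >= 1 - tol & ry <= nr + tol & rx >= 1 - tol & rx <= nc + tol
  if (!any(ok)) return(out)
  y <- pmin(pmax(ry[ok], 1), nr); x <- pmin(pmax(rx[ok], 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  if (nr == 1L) y0 <- rep(1L, length(y))
  if (nc == 1L) x0 <- rep(1L, length(x))
  fy <- y - y0; fx <- x - x0
  y1 <- pmin(y0 + 1L, nr); x1 <- pmin(x0 + 1L, nc)
  v <- (1 - fy) * (1 - fx) * img[cbind(y0, x0)] +
       (1 - fy) * fx       * img[cbind(y0, x1)] +
       fy       * (1 - fx) * img[cbind(y1, x0)] +
       fy       * fx       * img[cbind(y1, x1)]
  out[ok] <- v
  out
}

nearest_sample <- function(img, ry, rx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(ry))
  ok <- is.finite(ry) & is.finite(rx) &
    ry >= 0.5 - 1e-6 & ry <= nr + 0.5 & rx >= 0.5 - 1e-6 & rx <= nc + 0.5
  if (!any(ok)) return(out)
  i <- pmin(pmax(round(ry[ok]), 1L), nr)
  j <- pmin(pmax(round(rx[ok]), 1L), nc)
  out[ok] <- img[cbind(i, j)]
  out
}

ellipse_mask <- function(shape, center, semi) {
  if (any(semi <= 0)) return(matrix(FALSE, shape[1], shape[2]))
  ry <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  rx <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  outer(ry, rx, `+`) <= 1
}

is_binary_values <- function(g) {
  v <- g[!is.na(g)]
  all(v %in% c(0, 1))
}
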