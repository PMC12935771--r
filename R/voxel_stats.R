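#' Voxel-wise statistics
#'
#' SUVR computation, SUVR-thresholded ROI construction, paired voxel
#' extraction, Spearman correlations, Wilcoxon rank-sum comparisons, the
#' fixed m0-m6 nested regression suite compared by AIC with VIF
#' collinearity diagnostics, and rectangular hexbin-style voxel count
#' summaries.
#'
#' @name voxel_stats
NULL

MODEL_SUITE <- list(m0 = c("ptau", "iron", "maob"),
                    m1 = c("ptau", "iron"),
                    m2 = c("ptau", "maob"),
                    m3 = c("iron", "maob"),
                    m4 = "ptau",
                    m5 = "iron",
                    m6 = "maob")

#' Compute an SUVR volume from activity and a reference region
#'
#' Voxelwise activity divided by the mean activity within the reference
#' mask (here a stand-in for MRI-defined inferior cerebellar gray
#' matter).
#'
#' @param activity a `volume3d` of tracer activity
#' @param reference_mask a `volume3d` or logical/0-1 array, same shape
#' @return a `volume3d` of SUVR
#' @export
compute_suvr <- function(activity, reference_mask) {
  stopifnot(inherits(activity, "volume3d"))
  ref <- if (inherits(reference_mask, "volume3d")) reference_mask$grid else reference_mask
  if (!identical(dim(activity$grid), dim(ref)))
    stop("activity and reference mask shapes differ")
  sel <- !is.na(ref) & ref > 0
  if (!any(sel)) stop("reference mask is empty")
  m <- mean(activity$grid[sel], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("reference region mean activity must be positive")
  new_volume3d(activity$grid / m, activity$spacing, activity$origin)
}

#' Build an SUVR-thresholded ROI mask
#'
#' A voxel is included iff its SUVR is strictly greater than the
#' threshold (a voxel exactly at threshold is excluded), it lies inside
#' the anatomical mask, and -- if `structure_labels` is given -- inside
#' one of the named structures of the label volume.
#'
#' @param suvr a `volume3d`
#' @param threshold SUVR cutoff (> 0); 1.2 is the conventional
#'   positivity cutoff, with 1.3 and 1.4 used for sensitivity analyses
#' @param anatomical_mask array or `volume3d`, same shape
#' @param label_volume optional integer label array (same shape)
#' @param structure_labels optional character vector of region names
#' @param labels named legend mapping region names to integers (needed
#'   with `structure_labels`)
#' @return a `volume3d` 0/1 mask; attribute `"empty_warning"` is TRUE if
#'   no voxel survived
#' @export
build_roi_mask <- function(suvr, threshold = 1.2, anatomical_mask,
                           label_volume = NULL, structure_labels = NULL,
                           labels = NULL) {
  stopifnot(inherits(suvr, "volume3d"))
  if (threshold <= 0) stop("threshold must be positive")
  anat <- if (inherits(anatomical_mask, "volume3d")) anatomical_mask$grid else anatomical_mask
  if (!identical(dim(suvr$grid), dim(anat))) stop("anatomical mask shape mismatch")
  roi <- !is.na(suvr$grid) & suvr$grid > threshold & !is.na(anat) & anat > 0
  if (!is.null(structure_labels)) {
    if (is.null(label_volume) || is.null(labels))
      stop("structure_labels requires label_volume and a labels legend")
    lv <- if (inherits(label_volume, "volume3d")) label_volume$grid else label_volume
    roi <- roi & (lv %in% labels[structure_labels])
  }
  out <- new_volume3d(roi * 1L, suvr$spacing, suvr$origin)
  attr(out, "empty_warning") <- !any(roi)
  if (!any(roi)) warning("ROI is empty at SUVR threshold ", threshold)
  out
}

#' Extract the paired voxel table for an ROI
#'
#' One row per ROI voxel: SUVR, per-marker burden (NA where a marker is
#' unavailable or invalid at that voxel -- missing, never zero-imputed),
#' region name, and voxel indices.
#'
#' @param suvr a `volume3d`
#' @param burdens named list of marker burden `volume3d`s/arrays (NULL
#'   entries allowed for markers absent in a case)
#' @param roi_mask 0/1 array or `volume3d`
#' @param label_volume integer label array, same shape
#' @param labels named legend (integer values, region names)
#' @return data.frame with columns voxel_i, voxel_j, voxel_k, suvr, one
#'   column per marker, region
#' @export
extract_voxel_table <- function(suvr, burdens, roi_mask, label_volume,
                                labels = REGION_LABELS) {
  stopifnot(inherits(suvr, "volume3d"))
  roi <- if (inherits(roi_mask, "volume3d")) roi_mask$grid else roi_mask
  lv <- if (inherits(label_volume, "volume3d")) label_volume$grid else label_volume
  if (!identical(dim(suvr$grid), dim(roi)) ||
      !identical(dim(suvr$grid), dim(lv)))
    stop("geometry mismatch between volumes")
  sel <- which(!is.na(roi) & roi > 0)
  idx <- arrayInd(sel, dim(suvr$grid))
  out <- data.frame(voxel_i = idx[, 1], voxel_j = idx[, 2], voxel_k = idx[, 3],
                    suvr = suvr$grid[sel])
  for (m in names(burdens)) {
    b <- burdens[[m]]
    if (is.null(b)) { out[[m]] <- NA_real_; next }
    bg <- if (inherits(b, "volume3d")) b$grid else b
    if (!identical(dim(bg), dim(suvr$grid)))
      stop("geometry mismatch for marker '", m, "'")
    out[[m]] <- bg[sel]
  }
  out$region <- names(labels)[match(lv[sel], labels)]
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks (ties averaged), and
#' the p value comes from the t approximation with n - 2 degrees of
#' freedom (via `stats::cor.test`). Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors
#' @return object of class `correlation_result`: `rho`, `p_value`, `n`
#' @export
spearman_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero variance in ranks: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE, continuity = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum statistic with average ranks for ties; two-sided p value
#' from the tie-corrected normal approximation (via `stats::wilcox.test`
#' without continuity correction). The reported statistic is the
#' Mann-Whitney U for the first group.
#'
#' @param a,b numeric vectors (both non-empty; combined n >= 4 for the
#'   approximation to be meaningful)
#' @return list: `statistic` (U for `a`), `p_value`, `n` (per group)
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (length(a) + length(b) < 4)
    warning("combined n < 4: normal approximation is unreliable")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(a), length(b)))
}

spec_aic <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Fit the nested m0-m6 linear model suite
#'
#' Ordinary least squares with intercept for every model of the fixed
#' suite whose predictors are all available: m0 = all three markers,
#' m1 = ptau + iron, m2 = ptau + maob, m3 = iron + maob, m4/m5/m6 =
#' single markers. When ptau is unavailable (a non-tauopathy case) the
#' suite shrinks to m3, m5, m6 and m3 becomes the reference. All fits
#' use the identical pairwise-complete row set. AIC = n ln(RSS/n) + 2k
#' with k = predictors + 2 (intercept and error variance); AICc adds the
#' small-sample correction 2k(k+1)/(n-k-1). Delta AIC is relative to
#' the reference (full) model, and VIF = 1/(1 - R^2_j) is reported for
#' each reference-model predictor.
#'
#' @param table voxel table from [extract_voxel_table()] (needs `suvr`
#'   and one column per available marker)
#' @param available_markers markers to model (default the columns of
#'   `table` among ptau/iron/maob that are not entirely missing)
#' @param standardize if TRUE, z-score outcome and predictors before
#'   fitting (standardized betas for cross-case comparison)
#' @return object of class `model_suite_result`
#' @export
fit_model_suite <- function(table, available_markers = NULL,
                            standardize = FALSE) {
  all_markers <- intersect(MARKERS, names(table))
  if (is.null(available_markers))
    available_markers <- all_markers[vapply(all_markers, function(m)
      any(is.finite(table[[m]])), logical(1))]
  if (!length(available_markers)) stop("no available markers to model")

  cols <- c("suvr", available_markers)
  keep <- stats::complete.cases(table[cols]) &
    Reduce(`&`, lapply(table[cols], is.finite))
  df <- table[keep, cols, drop = FALSE]
  if (isTRUE(standardize)) df[] <- lapply(df, function(v) as.numeric(scale(v)))
  n <- nrow(df)

  models <- Filter(function(pr) all(pr %in% available_markers), MODEL_SUITE)
  if (!length(models)) stop("no applicable model in the suite")
  kmax <- max(lengths(models)) + 2L
  if (n <= kmax + 2L) stop("too few complete rows (", n, ") for the suite")

  fit_one <- function(id, preds) {
    fml <- stats::reformulate(preds, response = "suvr")
    fit <- stats::lm(fml, data = df)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design: collinear predictors among ",
           paste(preds, collapse = ", "))
    sm <- suppressWarnings(summary(fit))  # tolerate perfect noiseless fits
    rss <- sum(stats::residuals(fit)^2)
    k <- length(preds) + 2L
    aic <- spec_aic(rss, n, k)
    list(id = id,
         coefficients = stats::coef(fit),
         se = sm$coefficients[, "Std. Error"],
         p_values = sm$coefficients[, "Pr(>|t|)"],
         conf_int = stats::confint(fit),
         r_squared = sm$r.squared,
         rss = rss, n = n, k = k,
         aic = aic,
         aicc = aic + 2 * k * (k + 1) / (n - k - 1))
  }
  fits <- Map(fit_one, names(models), models)

  reference <- if ("m0" %in% names(fits)) "m0"
  else if ("m3" %in% names(fits)) "m3"
  else names(fits)[which.max(lengths(models))]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  delta_aic <- aics - aics[[reference]]

  ref_preds <- models[[reference]]
  vif <- if (length(ref_preds) < 2) {
    stats::setNames(rep(1, length(ref_preds)), ref_preds)
  } else {
    vapply(ref_preds, function(p) {
      r2 <- summary(stats::lm(stats::reformulate(setdiff(ref_preds, p),
                                                 response = p),
                              data = df))$r.squared
      1 / (1 - r2)
    }, numeric(1))
  }

  structure(list(fits = fits, delta_aic = delta_aic, vif = vif,
                 reference = reference,
                 best_model = names(which.min(aics)),
                 n = n, available_markers = available_markers,
                 standardized = isTRUE(standardize)),
            class = "model_suite_result")
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Summarize a model suite as a flat table
#'
#' One row per model with R-squared, AIC, AICc, delta AIC and per-marker
#' betas with significance stars -- the shape of a per-case results
#' table.
#'
#' @param x a `model_suite_result`
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.model_suite_result <- function(x, ...) {
  rows <- lapply(x$fits, function(f) {
    beta <- function(m) if (m %in% names(f$coefficients))
      sprintf("%.3f%s", f$coefficients[[m]],
              ifelse(signif_stars(f$p_values[[m]]) == "ns", "^ns",
                     signif_stars(f$p_values[[m]]))) else ""
    data.frame(model = f$id, n = f$n, r_squared = f$r_squared,
               aic = f$aic, aicc = f$aicc,
               delta_aic = x$delta_aic[[f$id]],
               beta_ptau = beta("ptau"), beta_iron = beta("iron"),
               beta_maob = beta("maob"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.model_suite_result <- function(x, ...) {
  cat("<model_suite_result> n =", x$n, " reference =", x$reference,
      " best =", x$best_model, "\n")
  print(as.data.frame(x), digits = 4)
  cat("VIF (", x$reference, "): ",
      paste(names(x$vif), signif(x$vif, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rectangular voxel-count binning of burden versus SUVR
#'
#' Counts voxels over a rectangular binning of (marker burden, SUVR),
#' the counting contract behind hexagonal-bin scatter summaries,
#' optionally restricted to a region stratum.
#'
#' @param table voxel table
#' @param marker marker column to bin on the x axis
#' @param n_bins number of bins per axis (>= 2)
#' @param stratum optional character vector of region names
#' @return list: `counts` (n_bins x n_bins matrix, burden by SUVR),
#'   `burden_edges`, `suvr_edges`, `n`
#' @export
hexbin_counts <- function(table, marker, n_bins = 20, stratum = NULL) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (!marker %in% names(table)) stop("unknown marker column '", marker, "'")
  df <- if (is.null(stratum)) table else table[table$region %in% stratum, ]
  if (nrow(df) == 0) stop("empty stratum: no voxels in ",
                          paste(stratum, collapse = ", "))
  df <- df[is.finite(df[[marker]]) & is.finite(df$suvr), ]
  if (nrow(df) == 0) stop("no voxels with finite '", marker, "' and SUVR")
  edges <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  }
  be <- edges(df[[marker]]); se <- edges(df$suvr)
  bi <- cut(df[[marker]], be, include.lowest = TRUE, labels = FALSE)
  si <- cut(df$suvr, se, include.lowest = TRUE, labels = FALSE)
  counts <- as.matrix(base::table(factor(bi, seq_len(n_bins)),
                                  factor(si, seq_len(n_bins))))
  dimnames(counts) <- NULL
  list(counts = counts, burden_edges = be, suvr_edges = se, n = nrow(df))
}
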