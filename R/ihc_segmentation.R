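#' Immunohistochemistry segmentation and threshold machinery
#'
#' Turns stain images or probability maps into binary positive-pixel
#' masks, with precision-recall / ROC machinery for choosing and
#' evaluating the operating threshold. The trainable pixel classifier is
#' a regularized logistic model on per-pixel intensity plus a small
#' multiscale local-mean feature bank, a deliberately simple stand-in
#' for Weka-style pixel classification of color-consistent stains.
#'
#' @name ihc_segmentation
NULL

build_pixel_features <- function(image, scales_um, pixel_size_um) {
  stopifnot(is.matrix(image))
  feats <- lapply(scales_um, function(s) {
    if (s <= 0) return(as.vector(image))
    as.vector(sep_conv(image, s / pixel_size_um))
  })
  X <- do.call(cbind, feats)
  colnames(X) <- paste0("mean_", scales_um, "um")
  X
}

#' Fit the stand-in pixel classifier
#'
#' Ridge-regularized logistic regression (via glmnet) on per-pixel
#' intensity and local means at a few spatial scales. Pixels are
#' subsampled (seeded, class-stratified) before fitting.
#'
#' @param training_images list of 2D numeric feature arrays
#' @param training_labels list of `binary_mask` objects (or 0/1
#'   matrices) aligned pixelwise with `training_images`
#' @param params list: `lambda` ridge penalty (default 1e-3),
#'   `scales_um` feature scales in micrometres (default 0: the raw
#'   intensity only, no spatial features; add scales such as
#'   `c(0, 100, 300)` for a Weka-style local-mean feature bank),
#'   `max_pixels` training subsample size (default 20000)
#' @param pixel_size_um micrometres per pixel of the training images
#' @param seed integer seed (subsampling)
#' @return serializable object of class `pixel_classifier`
#' @export
fit_pixel_classifier <- function(training_images, training_labels,
                                 params = list(), pixel_size_um = 10,
                                 seed = 1L) {
  if (!is.list(training_images)) training_images <- list(training_images)
  if (!is.list(training_labels)) training_labels <- list(training_labels)
  stopifnot(length(training_images) >= 1L,
            length(training_images) == length(training_labels))
  lambda <- params$lambda %||% 1e-3
  scales_um <- params$scales_um %||% 0
  max_pixels <- params$max_pixels %||% 20000L

  Xs <- list(); ys <- list()
  for (i in seq_along(training_images)) {
    img <- training_images[[i]]
    lab <- training_labels[[i]]
    labg <- if (inherits(lab, "binary_mask")) lab$grid else lab
    if (!identical(dim(img), dim(labg)))
      stop("training image ", i, " and its labels are not aligned pixelwise")
    if (!is_binary_values(labg)) stop("training labels must be binary")
    Xs[[i]] <- build_pixel_features(img, scales_um, pixel_size_um)
    ys[[i]] <- as.vector(labg)
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  keep <- !is.na(y) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot calibrate a classifier")

  idx <- with_seed(seed, {
    pos <- which(y == 1); neg <- which(y == 0)
    npos <- min(length(pos), ceiling(max_pixels / 2))
    nneg <- min(length(neg), max_pixels - npos)
    c(if (length(pos) > npos) sample(pos, npos) else pos,
      if (length(neg) > nneg) sample(neg, nneg) else neg)
  })
  beta <- if (ncol(X) >= 2L) {
    fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    as.numeric(stats::coef(fit))
  } else {
    # glmnet needs >= 2 columns; a single-feature model is an ordinary
    # logistic fit
    df <- data.frame(y = y[idx], x = X[idx, 1])
    as.numeric(stats::coef(suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial(), data = df))))
  }
  structure(list(coefficients = beta, scales_um = scales_um,
                 pixel_size_um = pixel_size_um, lambda = lambda),
            class = "pixel_classifier")
}

#' Predict per-pixel positive-class probabilities
#'
#' @param classifier a `pixel_classifier`
#' @param image 2D numeric array with the same feature semantics as the
#'   training images
#' @param pixel_size_um pitch of `image` (defaults to the training pitch)
#' @return a `probability_map` of the same shape as `image`
#' @export
predict_probability <- function(classifier, image, pixel_size_um = NULL) {
  stopifnot(inherits(classifier, "pixel_classifier"), is.matrix(image))
  pixel_size_um <- pixel_size_um %||% classifier$pixel_size_um
  X <- build_pixel_features(image, classifier$scales_um, pixel_size_um)
  if (ncol(X) + 1L != length(classifier$coefficients))
    stop("feature dimension mismatch between classifier and image")
  eta <- classifier$coefficients[1] +
    X %*% classifier$coefficients[-1]
  p <- stats::plogis(as.vector(eta))
  new_probability_map(matrix(p, nrow(image), ncol(image)), pixel_size_um)
}

#' Binarize a probability map at a threshold
#'
#' A pixel is positive iff its probability is greater than or equal to
#' the threshold (so p = 0.70 at threshold 0.7 is positive and p = 0.69
#' is background). NA probabilities become background.
#'
#' @param p a `probability_map`
#' @param threshold probability in \[0,1\]
#' @return a `binary_mask` with `threshold_used` recorded
#' @export
binarize_probability <- function(p, threshold) {
  stopifnot(inherits(p, "probability_map"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  g <- p$grid >= threshold
  g[is.na(g)] <- FALSE
  new_binary_mask(g * 1L, p$pixel_size_um, threshold)
}

#' Confusion counts, precision/recall/F1 and ROC AUC over thresholds
#'
#' For each requested threshold, pixels with probability >= t are
#' classified positive and compared against the truth mask by exhaustive
#' counting. The ROC AUC is integrated over the complete sweep of all
#' distinct probability values (trapezoidal rule, equivalent to the
#' rank-statistic form), independent of the user's threshold grid.
#'
#' @param p a `probability_map`
#' @param truth a `binary_mask` aligned with `p`
#' @param thresholds increasing thresholds in \[0,1\]
#' @return object of class `threshold_curve`: data.frame with columns
#'   threshold, tp, fp, fn, tn, precision, recall, f1, tpr, fpr and
#'   attribute `auc_roc`
#' @export
threshold_performance <- function(p, truth, thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(p, "probability_map"))
  tg <- if (inherits(truth, "binary_mask")) truth$grid else truth
  if (!identical(dim(p$grid), dim(tg)))
    stop("probability map and truth mask are not aligned")
  if (!is_binary_values(tg)) stop("truth mask must be binary")
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")

  keep <- !is.na(p$grid) & !is.na(tg)
  pv <- p$grid[keep]; tv <- tg[keep]
  pos <- pv[tv == 1]; neg <- pv[tv == 0]
  np <- length(pos); nn <- length(neg)

  rows <- lapply(thresholds, function(t) {
    tp <- sum(pos >= t); fp <- sum(neg >= t)
    c(tp = tp, fp = fp, fn = np - tp, tn = nn - fp)
  })
  cm <- do.call(rbind, rows)
  precision <- ifelse(cm[, "tp"] + cm[, "fp"] > 0,
                      cm[, "tp"] / (cm[, "tp"] + cm[, "fp"]), NA_real_)
  recall <- if (np > 0) cm[, "tp"] / np else rep(NA_real_, nrow(cm))
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), 0, NA_real_))
  fpr <- if (nn > 0) cm[, "fp"] / nn else rep(NA_real_, nrow(cm))

  auc <- if (np > 0 && nn > 0) {
    r <- rank(pv)  # average ranks: ties contribute 1/2, as in the
    (sum(r[tv == 1]) - np * (np + 1) / 2) /
      (as.numeric(np) * nn)  # full-sweep trapezoid
  } else NA_real_

  out <- data.frame(threshold = thresholds, tp = cm[, "tp"], fp = cm[, "fp"],
                    fn = cm[, "fn"], tn = cm[, "tn"], precision = precision,
                    recall = recall, f1 = f1, tpr = recall, fpr = fpr)
  structure(out, auc_roc = auc, class = c("threshold_curve", "data.frame"))
}

#' ROC AUC of a probability map against a truth mask
#'
#' Rank-statistic (full-sweep trapezoidal) AUC, without building the
#' per-threshold confusion table.
#'
#' @inheritParams threshold_performance
#' @return scalar AUC in \[0,1\]
#' @export
roc_auc <- function(p, truth) {
  pg <- if (inherits(p, "probability_map")) p$grid else p
  tg <- if (inherits(truth, "binary_mask")) truth$grid else truth
  if (!identical(dim(pg), dim(tg)))
    stop("probability map and truth mask are not aligned")
  keep <- !is.na(pg) & !is.na(tg)
  pv <- pg[keep]; tv <- tg[keep]
  np <- sum(tv == 1); nn <- sum(tv == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(pv)
  (sum(r[tv == 1]) - np * (np + 1) / 2) / (as.numeric(np) * nn)
}

#' Select the operating threshold from a threshold curve
#'
#' Returns the threshold maximizing the criterion (currently the F1
#' score). Rows with undefined F1 (no positive classifications) are
#' excluded; exact ties are broken toward the larger threshold, which
#' favors precision over recall.
#'
#' @param curve a `threshold_curve`
#' @param criterion currently only `"max_f1"`
#' @return the selected threshold
#' @export
select_operating_threshold <- function(curve, criterion = "max_f1") {
  stopifnot(inherits(curve, "threshold_curve"))
  criterion <- match.arg(criterion, "max_f1")
  ok <- !is.na(curve$f1)
  if (!any(ok)) stop("no threshold with a defined F1 score")
  f1 <- curve$f1[ok]; thr <- curve$threshold[ok]
  best <- max(f1)
  max(thr[f1 >= best - 1e-12])
}
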