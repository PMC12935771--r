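# build a (feature image, truth labels) pair where the intensity is a
# noisy rendering of the truth mask
staged_image <- function(truth, sd = 0.15, seed = 1) {
  with_seed(seed, {
    g <- 0.7 * truth$mask + 0.15 + rnorm(length(truth$mask), 0, sd)
    matrix(pmin(pmax(g, 0), 1), nrow(truth$mask))
  })
}

test_that("the pixel classifier separates stained from background pixels", {
  lmap <- tiny_phantom()
  tr_train <- generate_marker_truth(lmap, "iron", 100, seed = 3)
  tr_test <- generate_marker_truth(lmap, "iron", 100, seed = 4)
  img_train <- staged_image(tr_train, seed = 10)
  img_test <- staged_image(tr_test, seed = 11)

  clf <- fit_pixel_classifier(list(img_train),
                              list(new_binary_mask(tr_train$mask, 100)),
                              pixel_size_um = 100, seed = 1)
  p <- predict_probability(clf, img_test)
  expect_gte(roc_auc(p, new_binary_mask(tr_test$mask, 100)), 0.99)

  # identical refit gives identical predictions
  clf2 <- fit_pixel_classifier(list(img_train),
                               list(new_binary_mask(tr_train$mask, 100)),
                               pixel_size_um = 100, seed = 1)
  expect_identical(predict_probability(clf2, img_test)$grid, p$grid)

  # a strongly stained probe pixel scores above 0.5
  probe <- matrix(0.85, 32, 32)
  expect_true(all(predict_probability(clf, probe)$grid > 0.5))
})

test_that("permuted training labels collapse the classifier to chance", {
  # permutation null: labels independent of the image, at train and at
  # evaluation time, so ranking pixels by predicted probability cannot
  # beat chance
  lmap <- tiny_phantom()
  tr <- generate_marker_truth(lmap, "iron", 100, seed = 3)
  img <- staged_image(tr, seed = 10)
  perm <- with_seed(77, matrix(sample(tr$mask), nrow(tr$mask)))
  clf <- fit_pixel_classifier(list(img), list(new_binary_mask(perm, 100)),
                              pixel_size_um = 100, seed = 1)
  tr2 <- generate_marker_truth(lmap, "iron", 100, seed = 4)
  perm2 <- with_seed(78, matrix(sample(tr2$mask), nrow(tr2$mask)))
  auc <- roc_auc(predict_probability(clf, staged_image(tr2, seed = 11)),
                 new_binary_mask(perm2, 100))
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("classifier rejects degenerate training input", {
  img <- matrix(runif(100), 10)
  all_pos <- new_binary_mask(matrix(1L, 10, 10), 10)
  expect_error(fit_pixel_classifier(list(img), list(all_pos)),
               "single class")
  misaligned <- new_binary_mask(matrix(0:1, 4, 4), 10)
  expect_error(fit_pixel_classifier(list(img), list(misaligned)),
               "aligned")
})

test_that("probability predictions are well-formed", {
  img <- matrix(runif(400), 20)
  lab <- new_binary_mask((img > 0.5) * 1L, 10)
  clf <- fit_pixel_classifier(list(img), list(lab), pixel_size_um = 10)
  p <- predict_probability(clf, img)
  expect_identical(dim(p$grid), dim(img))
  expect_true(all(p$grid >= 0 & p$grid <= 1))
  # constant image -> constant probability map
  pc <- predict_probability(clf, matrix(0.4, 15, 15))
  expect_equal(length(unique(round(as.vector(pc$grid), 12))), 1L)
})

test_that("binarization uses >= at the threshold boundary", {
  p <- new_probability_map(matrix(c(0.70, 0.69, 0.0, 1.0), 2, 2), 10)
  m <- binarize_probability(p, 0.7)
  expect_identical(as.vector(m$grid), c(1L, 0L, 0L, 1L))
  expect_equal(m$threshold_used, 0.7)
  expect_true(all(binarize_probability(p, 0)$grid == 1L))
  expect_error(binarize_probability(p, 1.5), "\\[0, 1\\]")
})

test_that("threshold performance matches hand-counted confusion tables", {
  # 10x10 toy: 30 true positives, 10 false positives, 20 false negatives
  pv <- c(rep(0.9, 30), rep(0.9, 10), rep(0.1, 20), rep(0.1, 40))
  tv <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  p <- new_probability_map(matrix(pv, 10, 10), 10)
  truth <- new_binary_mask(matrix(tv, 10, 10), 10)
  curve <- threshold_performance(p, truth, thresholds = c(0.5))
  expect_equal(curve$tp, 30); expect_equal(curve$fp, 10)
  expect_equal(curve$precision, 0.75)
  expect_equal(curve$recall, 0.6)
  expect_equal(curve$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))

  # a probability map equal to its truth is a perfect classifier
  g <- with_seed(3, matrix(rbinom(144, 1, 0.4), 12))
  perf <- threshold_performance(new_probability_map(g + 0, 10),
                                new_binary_mask(g, 10),
                                thresholds = c(0.5))
  expect_equal(perf$precision, 1); expect_equal(perf$recall, 1)
  expect_equal(perf$f1, 1)
  expect_equal(attr(perf, "auc_roc"), 1)
})

test_that("confusion counts, rates and AUC agree with brute-force oracles", {
  for (seed in 1:6) {
    dims <- with_seed(seed, sample(4:12, 2))
    pg <- with_seed(seed + 10, matrix(round(runif(prod(dims)), 2),
                                      dims[1]))  # rounded -> ties occur
    tg <- with_seed(seed + 20, matrix(rbinom(prod(dims), 1, 0.4), dims[1]))
    p <- new_probability_map(pg, 10)
    truth <- new_binary_mask(tg, 10)
    thr <- seq(0, 1, by = 0.05)
    curve <- threshold_performance(p, truth, thresholds = thr)
    n <- prod(dims)
    for (i in seq_along(thr)) {
      bc <- brute_confusion(as.vector(pg), as.vector(tg), thr[i])
      expect_equal(unlist(curve[i, c("tp", "fp", "fn", "tn")]),
                   bc[c("tp", "fp", "fn", "tn")])
      expect_equal(sum(bc), n)  # conservation
    }
    expect_equal(attr(curve, "auc_roc"),
                 brute_auc(as.vector(pg), as.vector(tg)), tolerance = 1e-12)
    # recall/FPR are non-increasing in the threshold
    expect_true(all(diff(curve$tpr) <= 1e-12))
    expect_true(all(diff(curve$fpr) <= 1e-12))
  }
})

test_that("AUC equals the rank-sum statistic on tie-free data", {
  pg <- with_seed(5, matrix(sample(seq(0.01, 0.99, length.out = 100)), 10))
  tg <- with_seed(6, matrix(rbinom(100, 1, 0.5), 10))
  curve <- threshold_performance(new_probability_map(pg, 10),
                                 new_binary_mask(tg, 10))
  expect_equal(attr(curve, "auc_roc"),
               brute_auc(as.vector(pg), as.vector(tg)), tolerance = 1e-9)
})

test_that("uninformative probabilities give chance-level AUC", {
  pg <- with_seed(9, matrix(runif(1e4), 100))
  tg <- with_seed(10, matrix(rbinom(1e4, 1, 0.5), 100))
  auc <- roc_auc(new_probability_map(pg, 10), new_binary_mask(tg, 10))
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("operating-threshold selection maximizes F1 with ties toward precision", {
  mk_curve <- function(thresholds, f1) {
    df <- data.frame(threshold = thresholds, tp = 1, fp = 1, fn = 1, tn = 1,
                     precision = 0.5, recall = 0.5, f1 = f1,
                     tpr = 0.5, fpr = 0.5)
    structure(df, auc_roc = 0.5, class = c("threshold_curve", "data.frame"))
  }
  expect_equal(select_operating_threshold(mk_curve(0.4, 0.8)), 0.4)
  expect_equal(select_operating_threshold(
    mk_curve(c(0.3, 0.5, 0.7), c(0.2, 0.9, 0.4))), 0.5)
  expect_equal(select_operating_threshold(
    mk_curve(c(0.4, 0.6), c(0.7, 0.7))), 0.6)
  expect_error(select_operating_threshold(
    mk_curve(c(0.2, 0.8), c(NA_real_, NA_real_))), "F1")
})
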