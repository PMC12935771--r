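mk_vol <- function(grid) new_volume3d(grid)

test_that("SUVR normalization divides by the reference mean", {
  act <- mk_vol(array(5, c(4, 4, 2)))
  ref <- array(0L, c(4, 4, 2)); ref[1:2, 1, 1] <- 1L
  s <- compute_suvr(act, ref)
  expect_true(all(s$grid == 1))

  # activity 2.4 against a reference region whose mean activity is 2.0
  g2 <- array(2.4, c(3, 3, 1))
  ref2 <- array(0L, c(3, 3, 1)); ref2[3, , 1] <- 1L
  g2[ref2 == 1L] <- 2.0
  s2 <- compute_suvr(mk_vol(g2), ref2)
  expect_equal(s2$grid[1, 1, 1], 1.2)

  a3 <- mk_vol(array(with_seed(1, runif(200, 1, 3)), c(10, 10, 2)))
  r3 <- array(0L, c(10, 10, 2)); r3[, , 1] <- 1L
  s3 <- compute_suvr(a3, r3)
  expect_lt(abs(mean(s3$grid[r3 == 1]) - 1), 1e-9)

  expect_error(compute_suvr(mk_vol(array(0, c(3, 3, 1))),
                            array(1L, c(3, 3, 1))), "positive")
  expect_error(compute_suvr(a3, array(0L, c(10, 10, 2))), "empty")
})

test_that("SUVR ROIs use a strict threshold and nest across cutoffs", {
  g <- array(c(1.21, 1.20, 1.19, 2.0), c(2, 2, 1))
  anat <- array(1L, c(2, 2, 1))
  roi <- build_roi_mask(mk_vol(g), 1.2, anat)
  expect_equal(as.vector(roi$grid), c(1L, 0L, 0L, 1L))

  vol <- mk_vol(array(with_seed(5, runif(4000, 0.8, 1.8)), c(20, 20, 10)))
  counts <- vapply(c(1.2, 1.3, 1.4), function(t)
    sum(build_roi_mask(vol, t, array(1L, c(20, 20, 10)))$grid), numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(empty <- build_roi_mask(vol, 99, array(1L, c(20, 20, 10))),
                 "empty")
  expect_true(attr(empty, "empty_warning"))
  expect_error(build_roi_mask(vol, -1, array(1L, c(20, 20, 10))), "positive")
})

test_that("voxel tables pair SUVR, burdens and regions faithfully", {
  dims <- c(6, 5, 3)
  suvr <- mk_vol(array(with_seed(2, runif(prod(dims), 1, 2)), dims))
  burdens <- list(ptau = array(with_seed(3, runif(prod(dims))), dims),
                  iron = array(with_seed(4, runif(prod(dims))), dims),
                  maob = NULL)
  lab <- array(1L, dims); lab[1:2, , ] <- 2L
  labels <- c(background = 0L, cortex = 1L, white_matter = 2L)
  roi <- array(1L, dims)

  tab <- extract_voxel_table(suvr, burdens, roi, lab, labels)
  expect_equal(nrow(tab), prod(dims))
  expect_true(all(is.na(tab$maob)))  # missing marker stays missing

  picks <- with_seed(6, sample(nrow(tab), 20))
  for (r in picks) {
    i <- tab$voxel_i[r]; j <- tab$voxel_j[r]; k <- tab$voxel_k[r]
    expect_equal(tab$suvr[r], suvr$grid[i, j, k])
    expect_equal(tab$ptau[r], burdens$ptau[i, j, k])
    expect_equal(tab$region[r], names(labels)[match(lab[i, j, k], labels)])
  }

  one <- array(0L, dims); one[3, 2, 1] <- 1L
  tab1 <- extract_voxel_table(suvr, burdens, one, lab, labels)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$suvr, suvr$grid[3, 2, 1])

  expect_error(extract_voxel_table(suvr, list(ptau = array(0, c(2, 2, 2))),
                                   roi, lab, labels), "mismatch")
})

test_that("Spearman correlation matches hand-rank computations", {
  x <- 1:20
  expect_equal(spearman_corr(x, exp(x / 3))$rho, 1)
  expect_equal(spearman_corr(x, -x + 100)$rho, -1)

  # tie-free n = 5 fixture: rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
  r <- spearman_corr(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  d2 <- sum((rank(c(1, 2, 3, 4, 5)) - rank(c(2, 1, 4, 3, 5)))^2)
  expect_equal(r$rho, 1 - 6 * d2 / (5 * 24))
  expect_equal(r$n, 5)

  # seeded small fixtures with ties against the rank-Pearson oracle
  for (seed in 1:8) {
    n <- with_seed(seed, sample(4:8, 1))
    x <- with_seed(seed + 10, sample(1:4, n, replace = TRUE))
    y <- with_seed(seed + 20, sample(1:4, n, replace = TRUE))
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman_corr(x, y)$rho, brute_spearman_rho(x, y),
                 tolerance = 1e-12)
  }

  expect_error(spearman_corr(c(1, 2), c(3, 4)), "3")
  expect_error(spearman_corr(rep(1, 5), 1:5), "variance")
  # incomplete pairs are dropped pairwise
  expect_equal(spearman_corr(c(1, 2, NA, 4, 5), c(5, 4, 3, 2, NA))$n, 3)
})

test_that("Wilcoxon rank-sum matches exhaustive pair counting", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)  # U for the first group

  w2 <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(w2$statistic, 9)

  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  for (seed in 1:8) {
    na <- with_seed(seed, sample(2:4, 1))
    nb <- with_seed(seed + 5, sample(2:4, 1))
    a <- with_seed(seed + 10, sample(1:5, na, replace = TRUE))
    b <- with_seed(seed + 20, sample(1:5, nb, replace = TRUE))
    expect_equal(wilcoxon_rank_sum(a, b)$statistic,
                 brute_mann_whitney_u(a, b))
  }

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("the model suite fits, ranks and diagnoses the fixed models", {
  n <- 400
  tab <- with_seed(21, data.frame(ptau = runif(n), iron = runif(n),
                                  maob = runif(n)))
  tab$suvr <- 1 + 1.0 * tab$ptau + with_seed(22, rnorm(n, 0, 1e-8))
  suite <- fit_model_suite(tab)

  expect_named(suite$fits, paste0("m", 0:6))
  expect_equal(suite$delta_aic[["m0"]], 0)
  # nested-model RSS monotonicity
  rss <- vapply(suite$fits, `[[`, numeric(1), "rss")
  expect_true(all(rss >= rss[["m0"]] - 1e-12))
  # in the noiseless ptau-only world, m4 ties m0 on fit and wins on
  # parsimony via the AIC penalty
  expect_lt(abs(rss[["m4"]] - rss[["m0"]]) / rss[["m0"]], 0.05)
  expect_lt(suite$fits$m4$aic, suite$fits$m0$aic)
  expect_true(all(vapply(suite$fits, function(f) f$aicc >= f$aic,
                         logical(1))))
  expect_true(all(vapply(suite$fits, function(f)
    f$r_squared >= 0 && f$r_squared <= 1, logical(1))))

  # delta AIC agrees with the stats::AIC deltas (different constant,
  # identical differences)
  ref_fit <- lm(suvr ~ ptau + iron + maob, tab)
  m5_fit <- lm(suvr ~ iron, tab)
  expect_equal(suite$delta_aic[["m5"]],
               stats::AIC(m5_fit) - stats::AIC(ref_fit), tolerance = 1e-8)
})

test_that("VIF reflects predictor correlation exactly", {
  n <- 300
  tab <- with_seed(30, data.frame(ptau = rnorm(n)))
  tab$iron <- with_seed(31, rnorm(n))
  tab$maob <- with_seed(32, rnorm(n))
  # orthogonalize (including the intercept) via QR: all VIF exactly 1
  q <- qr.Q(qr(cbind(1, tab$ptau, tab$iron, tab$maob)))
  tab$ptau <- q[, 2]; tab$iron <- q[, 3]; tab$maob <- q[, 4]
  tab$suvr <- 1 + tab$ptau + with_seed(33, rnorm(n, 0, 0.1))
  suite <- fit_model_suite(tab)
  expect_equal(unname(suite$vif), rep(1, 3), tolerance = 1e-9)

  # r = 0.6 between two predictors: VIF = 1 / (1 - 0.36) = 1.5625
  n2 <- 5000
  z <- with_seed(34, rnorm(n2))
  x <- sqrt(0.6) * z + sqrt(0.4) * with_seed(35, rnorm(n2))
  y <- sqrt(0.6) * z + sqrt(0.4) * with_seed(36, rnorm(n2))
  tab2 <- data.frame(iron = x, maob = y)
  tab2$suvr <- 1 + 0.5 * x + with_seed(37, rnorm(n2, 0, 0.2))
  suite2 <- fit_model_suite(tab2, available_markers = c("iron", "maob"))
  expect_lt(abs(suite2$vif[["iron"]] - 1.5625), 0.05)
  expect_lt(abs(suite2$vif[["maob"]] - 1.5625), 0.05)

  # agreement with car's VIF on the full model
  cv <- car::vif(lm(suvr ~ iron + maob, tab2))
  expect_equal(unname(suite2$vif), unname(cv), tolerance = 1e-10)
})

test_that("a missing marker shrinks the suite instead of being imputed", {
  n <- 200
  tab <- with_seed(40, data.frame(ptau = NA_real_, iron = runif(n),
                                  maob = runif(n)))
  tab$suvr <- 1 + 0.5 * tab$iron + with_seed(41, rnorm(n, 0, 0.1))
  suite <- fit_model_suite(tab)
  expect_named(suite$fits, c("m3", "m5", "m6"))
  expect_equal(suite$reference, "m3")
  expect_equal(suite$delta_aic[["m3"]], 0)

  dup <- data.frame(ptau = tab$iron, iron = tab$iron, maob = tab$maob,
                    suvr = tab$suvr)
  expect_error(fit_model_suite(dup), "collinear")
})

test_that("hexbin counts conserve voxels over the binning", {
  tab <- data.frame(suvr = c(1.3), ptau = c(0.2), iron = 0.1, maob = 0.1,
                    region = "cortex")
  h1 <- hexbin_counts(tab, "ptau", n_bins = 3)
  expect_equal(sum(h1$counts), 1)

  # four points in the corners of a 2x2 binning
  tab4 <- data.frame(suvr = c(1, 1, 2, 2), ptau = c(0, 1, 0, 1),
                     region = "cortex")
  h4 <- hexbin_counts(tab4, "ptau", n_bins = 2)
  expect_true(all(h4$counts == 1))

  tabn <- with_seed(50, data.frame(suvr = runif(500, 1, 3),
                                   ptau = runif(500),
                                   region = sample(c("cortex",
                                                     "white_matter"),
                                                   500, TRUE)))
  h <- hexbin_counts(tabn, "ptau", n_bins = 10)
  expect_equal(sum(h$counts), 500)
  hw <- hexbin_counts(tabn, "ptau", n_bins = 10, stratum = "white_matter")
  expect_equal(sum(hw$counts), sum(tabn$region == "white_matter"))

  expect_error(hexbin_counts(tabn, "ptau", stratum = "lentiform"),
               "empty stratum")
  expect_error(hexbin_counts(tabn, "ptau", n_bins = 1), ">= 2")
})
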