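test_that("label map generation is deterministic, seeded, and covers every region", {
  a <- generate_label_map(c(64, 64), 1, seed = 7)
  b <- generate_label_map(c(64, 64), 1, seed = 7)
  expect_identical(a$grid, b$grid)
  expect_true(all(a$labels %in% a$grid))
  expect_setequal(names(a$labels),
                  c("background", "cortex", "white_matter", "lentiform",
                    "hippocampus"))
  # every cell carries exactly one label from the legend
  expect_true(all(a$grid %in% a$labels))

  c <- generate_label_map(c(64, 64), 1, seed = 8)
  expect_false(identical(a$grid, c$grid))

  expect_error(generate_label_map(c(16, 64), 1, seed = 1), "32")
})

test_that("marker masks hit the requested per-region densities", {
  lmap <- tiny_phantom()
  labels_px <- histopet:::label_grid_at_pixels(lmap, 50)
  for (marker in c("ptau", "iron", "maob")) {
    tr <- generate_marker_truth(lmap, marker, pixel_size_um = 50, seed = 3)
    spec <- histopet:::default_density_spec(marker)
    for (region in names(spec)) {
      sel <- labels_px == lmap$labels[[region]]
      if (sum(sel) < 100) next
      got <- mean(tr$mask[sel])
      if (spec[[region]] == 0) expect_equal(got, 0)
      else expect_lt(abs(got - spec[[region]]) / spec[[region]], 0.2)
    }
    expect_true(all(tr$mask %in% c(0L, 1L)))
  }
  # determinism
  t1 <- generate_marker_truth(lmap, "iron", 50, seed = 5)
  t2 <- generate_marker_truth(lmap, "iron", 50, seed = 5)
  expect_identical(t1$mask, t2$mask)
})

test_that("density calibration converges on large regions", {
  # a 400x400-cell cortex-dominated check at coarse pitch: fractions
  # within 5% relative of the specification
  lmap <- generate_label_map(c(400, 400), 1, seed = 2)
  spec <- c(background = 0, cortex = 0.2, white_matter = 0.1,
            lentiform = 0.3, hippocampus = 0.25)
  tr <- generate_marker_truth(lmap, "ptau", pixel_size_um = 1000,
                              density_spec = spec, seed = 4)
  for (region in c("cortex", "white_matter", "lentiform", "hippocampus")) {
    sel <- lmap$grid == lmap$labels[[region]]
    expect_lt(abs(mean(tr$mask[sel]) - spec[[region]]) / spec[[region]], 0.05)
  }
})

test_that("degenerate density specifications saturate correctly", {
  lmap <- tiny_phantom()
  zero <- generate_marker_truth(lmap, "ptau", 100,
                                density_spec = c(background = 0, cortex = 0,
                                                 white_matter = 0,
                                                 lentiform = 0,
                                                 hippocampus = 0),
                                seed = 1)
  expect_true(all(zero$mask == 0L))

  cortex_only <- generate_marker_truth(
    lmap, "ptau", 100,
    density_spec = c(background = 0, cortex = 1, white_matter = 0,
                     lentiform = 0, hippocampus = 0), seed = 1)
  labels_px <- histopet:::label_grid_at_pixels(lmap, 100)
  expect_identical(cortex_only$mask == 1L,
                   labels_px == lmap$labels[["cortex"]])

  expect_error(generate_marker_truth(lmap, "amyloid", 100), "unknown marker")
  expect_error(generate_marker_truth(lmap, "ptau", 100,
                                     density_spec = c(cortex = 1.4)),
               "\\[0, 1\\]")
})

test_that("probability corruption spans the noiseless limit to chance", {
  lmap <- tiny_phantom()
  tr <- generate_marker_truth(lmap, "ptau", 100, seed = 3)
  truth_mask <- new_binary_mask(tr$mask, 100)

  # noiseless point masses reproduce the truth at any threshold
  clean <- corrupt_to_probability(tr, pos_params = 1.0, neg_params = 0.0,
                                  seed = 1)
  for (t in c(0.1, 0.5, 0.9))
    expect_identical(binarize_probability(clean, t)$grid, tr$mask)

  # identical class distributions are chance-level
  flat <- corrupt_to_probability(tr, pos_params = c(2, 2),
                                 neg_params = c(2, 2), seed = 2)
  auc0 <- roc_auc(flat, truth_mask)
  expect_gt(auc0, 0.45); expect_lt(auc0, 0.55)

  # defaults give a well-separated map
  noisy <- corrupt_to_probability(tr, seed = 11)
  expect_gte(roc_auc(noisy, truth_mask), 0.8)
  expect_true(all(noisy$grid >= 0 & noisy$grid <= 1))

  # determinism
  expect_identical(corrupt_to_probability(tr, seed = 11)$grid, noisy$grid)

  expect_error(corrupt_to_probability(tr, pos_params = 1.5), "\\[0, 1\\]")
  expect_error(corrupt_to_probability(tr, pos_params = c(-1, 2)), "positive")
})

test_that("separation between class distributions drives AUC monotonically", {
  lmap <- tiny_phantom()
  tr <- generate_marker_truth(lmap, "maob", 100, seed = 6)
  truth_mask <- new_binary_mask(tr$mask, 100)
  pos_grid <- list(c(2, 5), c(4, 3), c(8, 2))  # increasing separation from Beta(2,5)
  aucs <- vapply(seq_along(pos_grid), function(i)
    roc_auc(corrupt_to_probability(tr, pos_params = pos_grid[[i]],
                                   neg_params = c(2, 5), seed = 20 + i),
            truth_mask), numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("PET synthesis is the stated linear model", {
  dims <- c(8, 8, 2)
  zero <- array(0, dims)
  half <- array(0.5, dims)

  v0 <- synthesize_pet(list(ptau = zero, iron = zero, maob = zero),
                       pet_ground_truth(noise_sd = 0, seed = 1))
  expect_equal(unique(as.vector(v0$grid)), 1.1)

  v1 <- synthesize_pet(list(ptau = half, iron = zero, maob = zero),
                       pet_ground_truth(betas = c(intercept = 1.0, ptau = 2.0,
                                                  iron = 0, maob = 0),
                                        noise_sd = 0, seed = 1))
  expect_equal(unique(as.vector(v1$grid)), 2.0)

  expect_error(synthesize_pet(list(ptau = half, iron = array(0, c(4, 4, 2)),
                                   maob = zero),
                              pet_ground_truth(noise_sd = 0)),
               "shape mismatch")

  # determinism of the noise draw
  gt <- pet_ground_truth(noise_sd = 0.1, seed = 9)
  expect_identical(synthesize_pet(list(ptau = half, iron = half,
                                       maob = half), gt)$grid,
                   synthesize_pet(list(ptau = half, iron = half,
                                       maob = half), gt)$grid)
})

test_that("refitting the full model on synthesized PET recovers the betas", {
  dims <- c(15, 15, 14)  # ~3000 voxels
  burdens <- with_seed(31, list(
    ptau = array(runif(prod(dims), 0, 0.5), dims),
    iron = array(runif(prod(dims), 0, 0.4), dims),
    maob = array(runif(prod(dims), 0, 0.4), dims)))
  truth <- c(intercept = 1.1, ptau = 0.7, iron = 0.4, maob = 0.0)
  suvr <- synthesize_pet(burdens, pet_ground_truth(betas = truth,
                                                   noise_sd = 0.1, seed = 8))
  df <- data.frame(suvr = as.vector(suvr$grid),
                   ptau = as.vector(burdens$ptau),
                   iron = as.vector(burdens$iron),
                   maob = as.vector(burdens$maob))
  fit <- summary(lm(suvr ~ ptau + iron + maob, df))$coefficients
  z <- (fit[, "Estimate"] - truth) / fit[, "Std. Error"]
  expect_true(all(abs(z) <= 3))
})

test_that("warping is exact in the identity and translation limits", {
  img <- matrix(0, 40, 40)
  img[10:20, 12:25] <- 1

  ident <- translation_warp(c(40, 40), c(0, 0))
  expect_equal(warp_image(img, ident, 1), img)
  wl <- warp_with_landmarks(img, ident, 1, n_landmarks = 8, seed = 2)
  expect_equal(wl$landmarks$src_x, wl$landmarks$dst_x)
  expect_equal(wl$landmarks$src_y, wl$landmarks$dst_y)

  shift <- translation_warp(c(40, 40), c(2, 0))
  ws <- warp_with_landmarks(img, shift, 1, n_landmarks = 8, seed = 2)
  expect_equal(ws$landmarks$dst_x - ws$landmarks$src_x, rep(2, 8))
  expect_equal(ws$landmarks$dst_y - ws$landmarks$src_y, rep(0, 8))
  # content shifts by 2 mm = 2 pixels: output(p) = input(p + 2mm in x)
  expect_equal(ws$warped[, 1:38], img[, 3:40])
})

test_that("random smooth warps displace landmarks and respect bounds", {
  warp <- random_smooth_warp(c(40, 40), max_disp_mm = 1.5,
                             landmark_jitter_sd = 0.1, seed = 5)
  img <- matrix(runif(40 * 40), 40)
  wl <- warp_with_landmarks(img, warp, 1, n_landmarks = 12, seed = 5)
  disp <- sqrt((wl$landmarks$dst_x - wl$landmarks$src_x)^2 +
               (wl$landmarks$dst_y - wl$landmarks$src_y)^2)
  expect_gt(mean(disp), 0)

  # landmarks pushed outside the image are an error listing the culprits
  big <- translation_warp(c(10, 10), c(5, 0))
  expect_error(warp_landmark_pairs(big, 8, seed = 1), "outside")

  # displacements above 10% of the field of view are refused
  too_big <- translation_warp(c(20, 20), c(4, 0))
  expect_error(warp_with_landmarks(img[1:20, 1:20], too_big, 1, seed = 1),
               "10%")
})
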