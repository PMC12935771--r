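#' Pipeline orchestration
#'
#' Runs the full synthetic study end to end -- simulate, segment,
#' quantify, resolution-match, register, threshold, analyze -- behind a
#' single flat configuration, with per-stage seeds, QC values and a
#' machine-readable report. Every stage draws its randomness from a
#' sub-seed derived from the master seed, so stages are reproducible in
#' isolation.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' All fixed analysis settings live here, never hard-coded in the
#' operations: segmentation probability threshold 0.7, percent-positive
#' tile 1 mm, PET resolution 5 mm FWHM, SUVR cutoffs 1.2/1.3/1.4
#' (strict), Dice QC bar 0.8. The phantom defaults describe a desk-scale
#' coronal slab: 48 x 48 mm, three 1 mm-spaced sections, 50 um pixel
#' pitch.
#'
#' @param seed master seed
#' @param out_dir artifact directory (NULL = no files written)
#' @return a nested configuration list
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    phantom = list(
      shape_mm = c(48, 48),
      spacing_mm = 1,
      n_sections = 3L,
      section_spacing_mm = 1,
      pixel_size_um = 50,
      densities = list(
        ptau = default_density_spec("ptau"),
        iron = default_density_spec("iron"),
        maob = default_density_spec("maob")),
      warp = list(n_control = 6L, max_disp_mm = 1.5, n_landmarks = 12L,
                  landmark_jitter_sd = 0.1),
      probability = list(pos = c(5, 2), neg = c(2, 5)),
      pet = list(betas = c(intercept = 1.1, ptau = 0.7, iron = 0.4,
                           maob = 0.0),
                 noise_sd = 0.1, pet_fwhm_mm = 5,
                 reference_activity = 2.0)),
    segmentation = list(prob_threshold = 0.7, iron_threshold = "auto_f1",
                        classifier = list(lambda = 1e-3,
                                          scales_um = c(0, 100, 300),
                                          max_pixels = 20000L)),
    quantify = list(tile_mm = 1, min_coverage = 0.5),
    registration = list(lambda = 0, dice_bar = 0.8),
    resolution = list(target_fwhm_mm = 5, tolerance = 0.02, max_iter = 25L),
    stats = list(suvr_thresholds = c(1.2, 1.3, 1.4), standardize = FALSE,
                 hexbin_bins = 20L))
}

#' Validate a run configuration
#'
#' Checks every module precondition implied by the configuration.
#' Violations are data, not exceptions: each element names the offending
#' field and the rule it breaks.
#'
#' @param config configuration list as from [default_config()]
#' @return character vector of violations (empty when valid)
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v

  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      !is.finite(config$seed))
    v <- c(v, "seed: must be a single finite number")
  ph <- config$phantom
  if (!is.null(ph)) {
    v <- add(any(ph$shape_mm / ph$spacing_mm < 32),
             "phantom.shape_mm: fewer than 32 cells per axis at this spacing")
    v <- add(ph$spacing_mm <= 0, "phantom.spacing_mm: must be positive")
    v <- add(ph$pixel_size_um <= 0, "phantom.pixel_size_um: must be positive")
    v <- add(ph$n_sections < 1, "phantom.n_sections: must be >= 1")
    for (m in names(ph$densities))
      if (any(ph$densities[[m]] < 0 | ph$densities[[m]] > 1))
        v <- c(v, paste0("phantom.densities.", m,
                         ": fractions must lie in [0, 1]"))
    pet <- ph$pet
    if (!is.null(pet)) {
      v <- add(pet$noise_sd < 0, "phantom.pet.noise_sd: must be >= 0")
      v <- add(pet$pet_fwhm_mm <= 0, "phantom.pet.pet_fwhm_mm: must be positive")
      if (is.null(names(pet$betas)) || names(pet$betas)[1] != "intercept")
        v <- c(v, "phantom.pet.betas: must be named with 'intercept' first")
    }
    w <- ph$warp
    if (!is.null(w)) {
      v <- add(w$landmark_jitter_sd < 0,
               "phantom.warp.landmark_jitter_sd: must be >= 0")
      v <- add(w$n_landmarks < 3, "phantom.warp.n_landmarks: must be >= 3")
      v <- add(w$max_disp_mm >= 0.1 * min(ph$shape_mm),
               "phantom.warp.max_disp_mm: must stay below 10% of the field of view")
    }
  }
  seg <- config$segmentation
  if (!is.null(seg)) {
    v <- add(seg$prob_threshold < 0 || seg$prob_threshold > 1,
             "segmentation.prob_threshold: probability must lie in [0, 1]")
    if (is.numeric(seg$iron_threshold) &&
        (seg$iron_threshold < 0 || seg$iron_threshold > 1))
      v <- c(v, "segmentation.iron_threshold: probability must lie in [0, 1]")
  }
  q <- config$quantify
  if (!is.null(q)) {
    v <- add(q$tile_mm < ph$pixel_size_um / 1000,
             "quantify.tile_mm: tile smaller than one pixel")
    v <- add(q$min_coverage <= 0 || q$min_coverage > 1,
             "quantify.min_coverage: must lie in (0, 1]")
  }
  r <- config$registration
  if (!is.null(r)) {
    v <- add(r$lambda < 0, "registration.lambda: must be >= 0")
    v <- add(r$dice_bar < 0 || r$dice_bar > 1,
             "registration.dice_bar: must lie in [0, 1]")
  }
  res <- config$resolution
  if (!is.null(res)) {
    v <- add(res$target_fwhm_mm <= 0,
             "resolution.target_fwhm_mm: must be positive")
    v <- add(res$tolerance <= 0, "resolution.tolerance: must be positive")
    v <- add(res$max_iter < 1, "resolution.max_iter: must be >= 1")
  }
  st <- config$stats
  if (!is.null(st)) {
    v <- add(any(st$suvr_thresholds <= 0),
             "stats.suvr_thresholds: SUVR cutoffs must be positive")
    v <- add(st$hexbin_bins < 2, "stats.hexbin_bins: must be >= 2")
  }
  v
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Simulate the synthetic case
#'
#' Generates the label map, per-section marker truth masks, section
#' warps with jittered landmarks, classifier-like probability maps and
#' an iron stain image (all in distorted section space), plus the
#' ground-truth burden volumes smoothed to the scanner FWHM and the
#' synthesized PET activity/SUVR volumes.
#'
#' @param config configuration list
#' @return simulation state list (consumed by the later stages)
#' @export
pipeline_simulate <- function(config) {
  ph <- config$phantom
  seed <- config$seed
  shape_cells <- round(ph$shape_mm / ph$spacing_mm)
  label_map <- generate_label_map(shape_cells, ph$spacing_mm,
                                  seed = sub_seed(seed, 1))
  labels_px <- label_grid_at_pixels(label_map, ph$pixel_size_um)
  tissue_px <- (labels_px > 0) * 1L
  pitch_mm <- ph$pixel_size_um / 1000

  sections <- vector("list", ph$n_sections)
  for (k in seq_len(ph$n_sections)) {
    base <- 100L * k
    truth <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
      generate_marker_truth(label_map, m, ph$pixel_size_um,
                            ph$densities[[m]],
                            seed = sub_seed(seed, base + match(m, MARKERS))))
    warp <- random_smooth_warp(ph$shape_mm, n_control = ph$warp$n_control,
                               max_disp_mm = ph$warp$max_disp_mm,
                               landmark_jitter_sd = ph$warp$landmark_jitter_sd,
                               seed = sub_seed(seed, base + 9L))
    landmarks <- warp_landmark_pairs(warp, ph$warp$n_landmarks,
                                     seed = sub_seed(seed, base + 10L))
    truth_section <- lapply(truth, function(tr) {
      g <- warp_image(tr$mask, warp, pitch_mm, interpolation = "nearest")
      new_binary_mask(g, ph$pixel_size_um)
    })
    prob_section <- lapply(c(ptau = "ptau", maob = "maob"), function(m) {
      tr <- truth_section[[m]]
      corrupt_to_probability(
        structure(list(marker = m, mask = tr$grid,
                       pixel_size_um = tr$pixel_size_um,
                       region_density = ph$densities[[m]]),
                  class = "marker_truth"),
        pos_params = ph$probability$pos, neg_params = ph$probability$neg,
        seed = sub_seed(seed, base + 20L + match(m, MARKERS)))
    })
    stain_iron <- with_seed(sub_seed(seed, base + 30L), {
      g <- 0.7 * truth_section$iron$grid + 0.15 +
        stats::rnorm(length(truth_section$iron$grid), 0, 0.12)
      matrix(pmin(pmax(g, 0), 1), nrow(truth_section$iron$grid))
    })
    tissue_section <- warp_image(tissue_px, warp, pitch_mm,
                                 interpolation = "nearest")
    sections[[k]] <- list(truth = truth, truth_section = truth_section,
                          prob_section = prob_section,
                          stain_iron = stain_iron,
                          tissue_section = tissue_section,
                          warp = warp, landmarks = landmarks)
  }

  # ground-truth burden volumes in PET space: percent-positive heatmaps
  # of the undistorted masks, smoothed in-plane to the scanner FWHM
  tile <- config$quantify$tile_mm
  sigma_px <- fwhm_to_sigma(ph$pet$pet_fwhm_mm) / tile
  oracle <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
    slices <- lapply(sections, function(sec) {
      h <- percent_positive_heatmap(
        new_binary_mask(sec$truth[[m]]$mask, ph$pixel_size_um),
        tile_mm = tile, min_coverage = config$quantify$min_coverage)
      smooth_2d(h$grid, sigma_px)
    })
    stack_sections(slices, ph$section_spacing_mm, tile)
  })

  gt <- pet_ground_truth(betas = ph$pet$betas, noise_sd = ph$pet$noise_sd,
                         pet_fwhm_mm = ph$pet$pet_fwhm_mm,
                         seed = sub_seed(seed, 500L))
  suvr_true <- synthesize_pet(oracle, pet_ground_truth(
    betas = ph$pet$betas, noise_sd = 0, pet_fwhm_mm = ph$pet$pet_fwhm_mm,
    seed = 0))
  suvr_noisy <- synthesize_pet(oracle, gt)

  label3d <- new_volume3d(
    array(rep(label_map$grid, ph$n_sections),
          dim = c(dim(label_map$grid), ph$n_sections)),
    c(label_map$spacing_mm, label_map$spacing_mm, ph$section_spacing_mm))
  tissue3d <- new_volume3d((label3d$grid > 0) * 1L, label3d$spacing)
  reference_mask <- new_volume3d((label3d$grid == 0) * 1L, label3d$spacing)
  activity_grid <- suvr_noisy$grid * ph$pet$reference_activity
  activity_grid[reference_mask$grid == 1L] <- ph$pet$reference_activity
  activity <- new_volume3d(activity_grid, label3d$spacing)

  list(label_map = label_map, label3d = label3d, tissue3d = tissue3d,
       sections = sections, oracle_burdens = oracle,
       suvr_true = suvr_true, gt = gt,
       activity = activity, reference_mask = reference_mask,
       seeds = list(label_map = sub_seed(seed, 1), pet = gt$seed))
}

#' Segment the simulated sections
#'
#' Binarizes the p-tau and MAO-B probability maps at the configured
#' probability threshold; trains the stand-in pixel classifier for iron
#' on the first section's stain image and truth labels, predicts
#' probability maps for every section, and picks the iron operating
#' threshold by maximum F1 over the precision-recall curve (or uses a
#' fixed configured value).
#'
#' @param sim state from [pipeline_simulate()]
#' @param config configuration list
#' @return segmentation state list
#' @export
pipeline_segment <- function(sim, config) {
  seg <- config$segmentation
  thr <- seg$prob_threshold

  iron_clf <- fit_pixel_classifier(
    list(sim$sections[[1]]$stain_iron),
    list(sim$sections[[1]]$truth_section$iron),
    params = seg$classifier,
    pixel_size_um = config$phantom$pixel_size_um,
    seed = sub_seed(config$seed, 600L))

  iron_prob1 <- predict_probability(iron_clf, sim$sections[[1]]$stain_iron)
  iron_curve <- threshold_performance(iron_prob1,
                                      sim$sections[[1]]$truth_section$iron)
  iron_thr <- if (is.numeric(seg$iron_threshold)) seg$iron_threshold
              else select_operating_threshold(iron_curve)

  sections <- lapply(seq_along(sim$sections), function(k) {
    sec <- sim$sections[[k]]
    iron_prob <- if (k == 1L) iron_prob1 else
      predict_probability(iron_clf, sec$stain_iron)
    masks <- list(
      ptau = binarize_probability(sec$prob_section$ptau, thr),
      iron = binarize_probability(iron_prob, iron_thr),
      maob = binarize_probability(sec$prob_section$maob, thr))
    auc <- c(ptau = roc_auc(sec$prob_section$ptau, sec$truth_section$ptau),
             iron = roc_auc(iron_prob, sec$truth_section$iron),
             maob = roc_auc(sec$prob_section$maob, sec$truth_section$maob))
    list(masks = masks, auc = auc)
  })

  list(sections = sections, iron_threshold = iron_thr,
       iron_curve = iron_curve, classifier = iron_clf,
       auc = do.call(rbind, lapply(sections, `[[`, "auc")))
}

#' Quantify burden heatmaps per section
#'
#' @param sim state from [pipeline_simulate()]
#' @param seg state from [pipeline_segment()]
#' @param config configuration list
#' @return list with per-section marker heatmaps and tissue masks at
#'   heatmap resolution
#' @export
pipeline_quantify <- function(sim, seg, config) {
  tile <- config$quantify$tile_mm
  mc <- config$quantify$min_coverage
  lapply(seq_along(sim$sections), function(k) {
    hm <- lapply(seg$sections[[k]]$masks, percent_positive_heatmap,
                 tile_mm = tile, min_coverage = mc)
    tissue_hm <- percent_positive_heatmap(
      new_binary_mask(sim$sections[[k]]$tissue_section,
                      config$phantom$pixel_size_um),
      tile_mm = tile, min_coverage = mc)
    list(heatmaps = hm, tissue = (tissue_hm$grid >= 0.5) * 1L)
  })
}

#' Register section heatmaps into blockface space
#'
#' Fits a thin-plate spline per section from the (jittered) landmark
#' pairs, applies it to each marker heatmap by inverse mapping onto the
#' blockface grid, computes Dice QC between the registered tissue mask
#' and the reference tissue mask, and stacks sections into 3D burden
#' volumes.
#'
#' @param sim,quant upstream stage states
#' @param config configuration list
#' @return registration state list
#' @export
pipeline_register <- function(sim, quant, config) {
  tile <- config$quantify$tile_mm
  ph <- config$phantom
  out_shape <- round(ph$shape_mm / tile)
  ref_tissue_hm <- percent_positive_heatmap(
    new_binary_mask(label_grid_at_pixels(sim$label_map,
                                         ph$pixel_size_um) > 0,
                    ph$pixel_size_um),
    tile_mm = tile, min_coverage = config$quantify$min_coverage)
  ref_tissue <- (ref_tissue_hm$grid >= 0.5) * 1L

  regs <- lapply(seq_along(sim$sections), function(k) {
    lms <- sim$sections[[k]]$landmarks
    tps <- fit_tps(swap_landmarks(lms), lambda = config$registration$lambda)
    hm_reg <- lapply(quant[[k]]$heatmaps, apply_transform_2d,
                     transform = tps, out_shape = out_shape,
                     out_spacing_mm = tile, interpolation = "linear")
    tis <- apply_transform_2d(quant[[k]]$tissue, tps, out_shape, tile,
                              in_spacing_mm = tile,
                              interpolation = "nearest")
    tis[is.na(tis)] <- 0
    dice <- dice_coefficient(tis, ref_tissue,
                             qc_bar = config$registration$dice_bar)
    fitted <- tps_apply(tps, cbind(lms$dst_x, lms$dst_y))
    resid <- sqrt((fitted[, "x"] - lms$src_x)^2 +
                  (fitted[, "y"] - lms$src_y)^2)
    list(tps = tps, heatmaps = hm_reg, dice = dice,
         landmark_residual_mm = mean(resid))
  })

  volumes <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
    stack_sections(lapply(regs, function(r) r$heatmaps[[m]]),
                   ph$section_spacing_mm, tile))
  list(sections = regs, volumes = volumes,
       dice = vapply(regs, function(r) r$dice$value, numeric(1)),
       dice_pass = vapply(regs, function(r) r$dice$qc_pass, logical(1)),
       landmark_residual_mm = vapply(regs, `[[`, numeric(1),
                                     "landmark_residual_mm"))
}

#' Match heatmap resolution to the PET point-spread FWHM
#'
#' Estimates the in-plane smoothness of every registered burden slice
#' and smooths it up to the target FWHM with [blur_to_fwhm()]. Slices
#' already smoother than the target are left untouched with a warning
#' flag (smoothing cannot sharpen).
#'
#' @param reg state from [pipeline_register()]
#' @param config configuration list
#' @return list with matched `volumes` and per-marker `fwhm` diagnostics
#' @export
pipeline_resolution <- function(reg, config) {
  res <- config$resolution
  out <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
    vol <- reg$volumes[[m]]
    diag <- list()
    for (s in seq_len(dim(vol$grid)[3])) {
      slice <- vol$grid[, , s]
      est0 <- tryCatch(mean_fwhm(estimate_fwhm(slice, vol$spacing[1])),
                       error = function(e) NA_real_)
      if (is.na(est0)) {
        diag[[s]] <- list(before_mm = NA, after_mm = NA, skipped = TRUE,
                          warning = TRUE)
        next
      }
      if (est0 > res$target_fwhm_mm * (1 + res$tolerance)) {
        diag[[s]] <- list(before_mm = est0, after_mm = est0, skipped = TRUE,
                          warning = TRUE)
        next
      }
      b <- blur_to_fwhm(slice, vol$spacing[1], res$target_fwhm_mm,
                        tolerance = res$tolerance, max_iter = res$max_iter)
      vol$grid[, , s] <- b$field
      diag[[s]] <- list(before_mm = est0, after_mm = mean_fwhm(b$estimate),
                        skipped = FALSE, warning = b$warning)
    }
    list(volume = vol, diagnostics = diag)
  })
  list(volumes = lapply(out, `[[`, "volume"),
       fwhm = lapply(out, `[[`, "diagnostics"))
}

suite_report <- function(suite) {
  if (is.null(suite)) return(NULL)
  list(n = suite$n, reference = suite$reference, best_model = suite$best_model,
       delta_aic = as.list(suite$delta_aic),
       vif = as.list(suite$vif),
       r_squared = lapply(suite$fits, `[[`, "r_squared"),
       betas = lapply(suite$fits, function(f) as.list(f$coefficients)))
}

#' Voxel-wise statistical analysis of a simulated run
#'
#' Computes SUVR from the activity volume, builds SUVR-thresholded ROIs
#' at each configured cutoff, extracts voxel tables pairing SUVR with
#' the resolution-matched registered burdens, and runs the statistical
#' layer: per-marker Spearman correlations, the MAO-B in/out of white
#' matter Wilcoxon comparison, the m0-m6 AIC model suite (full ROI and
#' the lentiform sub-ROI), hexbin counts, and ground-truth recovery
#' diagnostics on the oracle burdens.
#'
#' @param sim,res upstream stage states
#' @param config configuration list
#' @return analysis list
#' @export
pipeline_analyze <- function(sim, res, config) {
  st <- config$stats
  suvr <- compute_suvr(sim$activity, sim$reference_mask)

  per_threshold <- lapply(st$suvr_thresholds, function(t) {
    roi <- suppressWarnings(build_roi_mask(suvr, t, sim$tissue3d))
    tab <- extract_voxel_table(suvr, res$volumes, roi, sim$label3d,
                               sim$label_map$labels)
    spearman <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
      tryCatch(unclass(spearman_corr(tab[[m]], tab$suvr)),
               error = function(e) NULL))
    suite <- tryCatch(fit_model_suite(tab, standardize = st$standardize),
                      error = function(e) NULL)
    list(threshold = t, n_voxels = nrow(tab), table = tab,
         spearman = spearman, suite = suite)
  })
  names(per_threshold) <- paste0("suvr_", st$suvr_thresholds)

  tab1 <- per_threshold[[1]]$table
  wm <- tab1$region == "white_matter"
  wilcoxon_maob_wm <- if (any(wm) && any(!wm))
    tryCatch(wilcoxon_rank_sum(tab1$maob[wm], tab1$maob[!wm]),
             error = function(e) NULL) else NULL

  lent_roi <- suppressWarnings(build_roi_mask(
    suvr, st$suvr_thresholds[1], sim$tissue3d,
    label_volume = sim$label3d, structure_labels = "lentiform",
    labels = sim$label_map$labels))
  lent_tab <- extract_voxel_table(suvr, res$volumes, lent_roi, sim$label3d,
                                  sim$label_map$labels)
  lentiform <- list(
    n_voxels = nrow(lent_tab),
    spearman_iron = tryCatch(unclass(spearman_corr(lent_tab$iron,
                                                   lent_tab$suvr)),
                             error = function(e) NULL))

  hexbin <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
    tryCatch(hexbin_counts(tab1, m, n_bins = st$hexbin_bins),
             error = function(e) NULL))

  # ground-truth recovery on the oracle burdens with the noiseless ROI:
  # the design is fixed by the true SUVR, so OLS recovery is unbiased
  roi_true <- suppressWarnings(build_roi_mask(sim$suvr_true,
                                              st$suvr_thresholds[1],
                                              sim$tissue3d))
  oracle_tab <- extract_voxel_table(suvr, sim$oracle_burdens, roi_true,
                                    sim$label3d, sim$label_map$labels)
  oracle_suite <- tryCatch(fit_model_suite(oracle_tab),
                           error = function(e) NULL)
  recovery <- if (!is.null(oracle_suite)) {
    est <- oracle_suite$fits$m0$coefficients
    truth <- sim$gt$betas
    names(truth)[1] <- "(Intercept)"
    err <- est - truth[names(est)]
    list(n_voxels = nrow(oracle_tab),
         beta_true = as.list(sim$gt$betas),
         beta_est = as.list(est),
         beta_error = as.list(err),
         max_abs_error = max(abs(err)))
  } else NULL

  list(suvr = suvr, per_threshold = per_threshold,
       roi_voxels = vapply(per_threshold, `[[`, numeric(1), "n_voxels"),
       wilcoxon_maob_wm = wilcoxon_maob_wm, lentiform = lentiform,
       hexbin = hexbin, recovery = recovery)
}

#' Run the full pipeline
#'
#' Executes simulate, segment, quantify, register, resolution-match and
#' analyze in order, optionally writing all artifacts (NIfTI volumes,
#' TIFF masks, CSV landmarks/tables, JSON transforms and report) to
#' `config$out_dir`, and returns the machine-readable run report. With a
#' fixed config and seed the report and every artifact are bit-identical
#' across runs.
#'
#' @param config configuration list from [default_config()] (possibly
#'   modified); validated before anything runs
#' @return an object of class `run_report` (a nested list); the full
#'   stage states are attached as attribute `"state"`
#' @export
run_pipeline <- function(config = default_config()) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))

  sim <- stage_error("simulate", pipeline_simulate(config))
  seg <- stage_error("segment", pipeline_segment(sim, config))
  quant <- stage_error("quantify", pipeline_quantify(sim, seg, config))
  reg <- stage_error("register", pipeline_register(sim, quant, config))
  res <- stage_error("resolution", pipeline_resolution(reg, config))
  ana <- stage_error("analyze", pipeline_analyze(sim, res, config))

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    stages = list(
      simulate = list(seed = config$seed,
                      n_sections = config$phantom$n_sections,
                      label_counts = as.list(base::table(
                        factor(sim$label_map$grid,
                               levels = sim$label_map$labels,
                               labels = names(sim$label_map$labels))))),
      segment = list(auc = apply(seg$auc, 2, stats::median),
                     iron_threshold = seg$iron_threshold,
                     prob_threshold = config$segmentation$prob_threshold),
      register = list(dice = reg$dice, dice_pass = reg$dice_pass,
                      dice_bar = config$registration$dice_bar,
                      landmark_residual_mm = reg$landmark_residual_mm),
      resolution = list(target_fwhm_mm = config$resolution$target_fwhm_mm,
                        fwhm = res$fwhm),
      analyze = list(
        roi_voxels = as.list(ana$roi_voxels),
        spearman = lapply(ana$per_threshold, `[[`, "spearman"),
        model_suite = lapply(ana$per_threshold,
                             function(p) suite_report(p$suite)),
        wilcoxon_maob_wm = ana$wilcoxon_maob_wm,
        lentiform = ana$lentiform,
        recovery = ana$recovery)))
  class(report) <- "run_report"
  attr(report, "state") <- list(sim = sim, seg = seg, quant = quant,
                                reg = reg, res = res, analyze = ana)

  if (!is.null(config$out_dir))
    write_run_artifacts(report, config)
  report
}

write_run_artifacts <- function(report, config) {
  state <- attr(report, "state")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- state$sim; ana <- state$analyze; reg <- state$reg; res <- state$res

  write_config_yaml(config[setdiff(names(config), "out_dir")],
                    file.path(out, "config.yaml"))
  write_volume_nifti(sim$label3d, file.path(out, "label_map.nii"))
  write_volume_nifti(ana$suvr, file.path(out, "suvr.nii"))
  for (m in MARKERS) {
    v <- res$volumes[[m]]
    v$grid[is.na(v$grid)] <- 0
    write_volume_nifti(v, file.path(out, paste0("burden_", m, ".nii")))
  }
  for (k in seq_along(sim$sections)) {
    write_landmarks_csv(sim$sections[[k]]$landmarks,
                        file.path(out, sprintf("landmarks_section%02d.csv", k)))
    write_tps_json(reg$sections[[k]]$tps,
                   file.path(out, sprintf("tps_section%02d.json", k)))
    write_image_tiff(state$seg$sections[[k]]$masks$ptau,
                     file.path(out, sprintf("mask_ptau_section%02d.tiff", k)))
  }
  tab <- ana$per_threshold[[1]]$table
  utils::write.csv(tab, file.path(out, "voxel_table.csv"), row.names = FALSE)
  suite <- ana$per_threshold[[1]]$suite
  if (!is.null(suite))
    utils::write.csv(as.data.frame(suite),
                     file.path(out, "model_suite.csv"), row.names = FALSE)
  write_report_json(unclass(report), file.path(out, "report.json"))
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  ROI voxels:",
      paste(names(x$stages$analyze$roi_voxels),
            unlist(x$stages$analyze$roi_voxels), sep = "=", collapse = ", "),
      "\n")
  cat("  Dice:", paste(signif(unlist(x$stages$register$dice), 3),
                       collapse = ", "), "\n")
  if (!is.null(x$stages$analyze$recovery))
    cat("  max |beta error| (oracle):",
        signif(x$stages$analyze$recovery$max_abs_error, 3), "\n")
  invisible(x)
}
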