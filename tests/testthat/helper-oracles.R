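# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, textbook formulas) and never call
# the implementation code paths they check.

# per-tile double-loop percent-positive counter
brute_heatmap <- function(mask_grid, pixel_size_um, tile_mm,
                          min_coverage = 0.5) {
  pitch <- pixel_size_um / 1000
  nr <- nrow(mask_grid); nc <- ncol(mask_grid)
  row_tile <- floor((seq_len(nr) - 0.5) * pitch / tile_mm) + 1
  col_tile <- floor((seq_len(nc) - 0.5) * pitch / tile_mm) + 1
  ntr <- max(row_tile); ntc <- max(col_tile)
  grid <- matrix(NA_real_, ntr, ntc)
  valid <- matrix(FALSE, ntr, ntc)
  full <- (tile_mm / pitch)^2
  for (a in seq_len(ntr)) {
    for (b in seq_len(ntc)) {
      rs <- which(row_tile == a); cs <- which(col_tile == b)
      tot <- length(rs) * length(cs)
      if (tot > 0) {
        pos <- sum(mask_grid[rs, cs, drop = FALSE])
        grid[a, b] <- pos / tot
        valid[a, b] <- tot / full >= min_coverage
      }
    }
  }
  list(grid = grid, valid = valid)
}

# explicit per-pixel confusion counting at one threshold
brute_confusion <- function(pv, tv, thr) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pv)) {
    pred <- pv[i] >= thr
    if (pred && tv[i] == 1) tp <- tp + 1
    else if (pred && tv[i] == 0) fp <- fp + 1
    else if (!pred && tv[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# probability-of-correct-ranking AUC over all positive/negative pairs
brute_auc <- function(pv, tv) {
  pos <- pv[tv == 1]; neg <- pv[tv == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Spearman rho as the Pearson correlation of average ranks
brute_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U for the first group by exhaustive pair counting
brute_mann_whitney_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b)
    u <- u + (x > y) + 0.5 * (x == y)
  u
}

# small default-density phantom shared by several tests
tiny_phantom <- function(seed = 7) generate_label_map(c(48, 48), 1, seed)

# closed-loop registration: distort the tissue mask with a known smooth
# warp, register it back from jittered landmarks, return Dice and the
# residual at true correspondences
closed_loop_registration <- function(seed, jitter_sd = 0.1,
                                     pixel_size_um = 200,
                                     n_landmarks = 12) {
  lmap <- generate_label_map(c(48, 48), 1, seed)
  tissue <- (histopet:::label_grid_at_pixels(lmap, pixel_size_um) > 0) * 1
  pitch <- pixel_size_um / 1000
  warp <- random_smooth_warp(c(48, 48), max_disp_mm = 1.5,
                             landmark_jitter_sd = jitter_sd, seed = seed)
  wl <- warp_with_landmarks(tissue, warp, pitch, n_landmarks,
                            seed = seed + 1000, interpolation = "nearest")
  tps <- fit_tps(swap_landmarks(wl$landmarks), lambda = 0)
  reg <- apply_transform_2d(wl$warped, tps, dim(tissue), pitch,
                            in_spacing_mm = pitch,
                            interpolation = "nearest")
  reg[is.na(reg)] <- 0
  # residual at the true (unjittered) correspondences of the landmarks
  true_dst <- histopet:::warp_eval(warp, wl$landmarks$src_x,
                                   wl$landmarks$src_y)
  back <- tps_apply(tps, true_dst)
  resid <- mean(sqrt((back[, "x"] - wl$landmarks$src_x)^2 +
                     (back[, "y"] - wl$landmarks$src_y)^2))
  list(dice = dice_coefficient(reg, tissue)$value, residual_mm = resid)
}
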