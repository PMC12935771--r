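# Artifact writers: NIfTI-1 for volumes, single-channel TIFF for masks
# and probability maps, CSV for landmarks and voxel tables, JSON for
# transforms, ground truth and run reports, YAML for configs.

#' Write a volume as NIfTI-1
#'
#' @param vol a `volume3d` (or array)
#' @param path output path (`.nii`; uncompressed for reproducible hashes)
#' @param spacing per-axis spacing when `vol` is a bare array
#' @return the path, invisibly
#' @export
write_volume_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "volume3d")) {
    grid <- vol$grid; spacing <- vol$spacing
  } else grid <- vol
  img <- RNifti::asNifti(grid, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file
#' @return a `volume3d`
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  new_volume3d(arr, RNifti::pixdim(img)[seq_len(3)])
}

#' Write a mask or probability map as single-channel TIFF
#'
#' Masks are written 8-bit, fractional maps 32-bit float; no
#' compression, so repeated runs give identical bytes.
#'
#' @param x `binary_mask`, `probability_map`, or numeric matrix in \[0,1\]
#' @param path output `.tiff` path
#' @return the path, invisibly
#' @export
write_image_tiff <- function(x, path) {
  g <- if (inherits(x, "binary_mask") || inherits(x, "probability_map"))
    x$grid else x
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  g[is.na(g)] <- 0
  bits <- if (is_binary_values(g)) 8L else 32L
  tiff::writeTIFF(g, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Write landmark pairs as CSV
#'
#' Columns src_x, src_y, dst_x, dst_y in mm.
#'
#' @param landmarks landmark data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(as_landmarks(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' Read landmark pairs from CSV
#'
#' @param path CSV with columns src_x, src_y, dst_x, dst_y
#' @return landmark data.frame
#' @export
read_landmarks_csv <- function(path) {
  as_landmarks(utils::read.csv(path))
}

#' Serialize a TPS transform to JSON
#'
#' @param transform a `tps_transform`
#' @param path output path
#' @return the path, invisibly
#' @export
write_tps_json <- function(transform, path) {
  stopifnot(inherits(transform, "tps_transform"))
  jsonlite::write_json(
    list(affine = transform$a, radial = transform$w,
         source_landmarks = transform$src, lambda = transform$lambda),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write a run report (or any nested list) as JSON
#'
#' @param report nested list of results
#' @param path output path
#' @return the path, invisibly
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' @param config run configuration list
#' @param path YAML path
#' @return the path (write) or the configuration list (read)
#' @export
write_config_yaml <- function(config, path) {
  # yaml serializes named atomic vectors as plain sequences, losing the
  # names; write them as maps instead
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else x
  }
  yaml::write_yaml(prep(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  # yaml reads numeric vectors back as lists; restore the vector-valued
  # config fields (unnamed numeric sequences, and the known named
  # numeric maps such as betas and per-region densities)
  vector_fields <- c("shape_mm", "suvr_thresholds", "betas", "pos", "neg",
                     "ptau", "iron", "maob", "shift_mm")
  normalize <- function(x, name = "") {
    if (!is.list(x)) return(x)
    scalar_num <- length(x) > 0 &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1L, logical(1)))
    if (scalar_num && (is.null(names(x)) || name %in% vector_fields))
      return(unlist(x))
    nm <- names(x) %||% rep("", length(x))
    for (i in seq_along(x))
      if (!is.null(x[[i]])) x[[i]] <- normalize(x[[i]], nm[i])
    x
  }
  normalize(yaml::read_yaml(path))
}
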