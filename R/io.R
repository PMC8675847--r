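#' Write a dual-energy image as NIfTI
#'
#' Volumes are written in conventional Hounsfield units (the stored CT'
#' offset is removed at this boundary). Two dialects: one file per energy
#' (`ct_low.nii` / `ct_high.nii`, the default) or a single 4-D file with
#' energy as the fourth axis.
#'
#' @param image A [dual_energy_image()].
#' @param dir Output directory (created if needed).
#' @param four_d Write one 4-D file instead of two 3-D files.
#' @return Invisibly, the file path(s) written.
#' @export
write_dual_energy <- function(image, dir, four_d = FALSE) {
  stopifnot(inherits(image, "dual_energy_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- image$protocol$voxel_size
  hu_low <- image$ct_low - image$offset
  hu_high <- image$ct_high - image$offset
  as_nii <- function(a) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- vx[seq_len(min(3L, length(dim(a))))]
    img
  }
  if (four_d) {
    d <- dim(hu_low)
    vol4 <- array(c(hu_low, hu_high), c(d, 2L))
    f <- file.path(dir, "ct_dual.nii")
    RNifti::writeNifti(as_nii(vol4), f)
    paths <- f
  } else {
    paths <- file.path(dir, c("ct_low.nii", "ct_high.nii"))
    RNifti::writeNifti(as_nii(hu_low), paths[1])
    RNifti::writeNifti(as_nii(hu_high), paths[2])
  }
  invisible(paths)
}

#' Read a dual-energy image from NIfTI
#'
#' Accepts either two 3-D volumes (low, high) or one 4-D volume with
#' energy as the fourth axis; files hold Hounsfield units and the CT'
#' offset is applied on read.
#'
#' @param low Path to the low-energy volume, or to a 4-D dual volume.
#' @param high Path to the high-energy volume (omit for the 4-D dialect).
#' @param protocol A [scan_protocol()]; voxel size is taken from the file
#'   header when available.
#' @param offset CT' shift to apply (default 1000).
#' @return A [dual_energy_image()].
#' @export
read_dual_energy <- function(low, high = NULL, protocol = scan_protocol(),
                             offset = 1000) {
  v1 <- RNifti::readNifti(low)
  px <- RNifti::pixdim(v1)
  if (length(px) >= 3 && all(px[1:3] > 0)) protocol$voxel_size <- px[1:3]
  if (is.null(high)) {
    if (length(dim(v1)) != 4L || dim(v1)[4] != 2L)
      stop("single-file input must be 4-D with energy as the 4th axis",
           call. = FALSE)
    a <- as.array(v1)
    ct_low <- a[, , , 1]; ct_high <- a[, , , 2]
  } else {
    ct_low <- as.array(v1)
    ct_high <- as.array(RNifti::readNifti(high))
  }
  dual_energy_image(ct_low + offset, ct_high + offset, protocol,
                    offset = offset)
}

#' Write material maps as NIfTI
#'
#' Gold and water concentration volumes in ug/ml (the external unit), plus
#' the body mask and any ROI labels as integer volumes.
#'
#' @param maps A [material_maps()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_material_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "material_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_nii <- function(a) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- maps$voxel_size
    img
  }
  paths <- c(file.path(dir, "c_au_ug_ml.nii"),
             file.path(dir, "c_water_ug_ml.nii"),
             file.path(dir, "mask.nii"))
  RNifti::writeNifti(as_nii(maps$c_au * 1000), paths[1])
  RNifti::writeNifti(as_nii(maps$c_water * 1000), paths[2])
  RNifti::writeNifti(as_nii(maps$mask * 1L), paths[3])
  if (!is.null(maps$labels)) {
    p <- file.path(dir, "labels.nii")
    RNifti::writeNifti(as_nii(maps$labels), p)
    paths <- c(paths, p)
    if (!is.null(maps$label_names)) {
      pn <- file.path(dir, "label_names.txt")
      writeLines(maps$label_names, pn)
      paths <- c(paths, pn)
    }
  }
  invisible(paths)
}

#' Write / read a sensitivity matrix as JSON
#'
#' All coefficient, intercept, fit-quality and conditioning fields are
#' serialized; [read_sensitivity()] reconstructs the object (recomputing
#' the condition number from the coefficients).
#'
#' @param fit A [sensitivity_matrix()].
#' @param path JSON file path.
#' @return `write_sensitivity()`: invisibly, `path`;
#'   `read_sensitivity()`: a [sensitivity_matrix()].
#' @export
write_sensitivity <- function(fit, path) {
  stopifnot(inherits(fit, "sensitivity_matrix"))
  out <- unclass(fit)
  out$condition_number <- NULL                     # derived, recomputed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(x) if (is.null(x)) NA_real_ else x
  sensitivity_matrix(
    e_au_low = j$e_au_low, e_au_high = j$e_au_high,
    e_w_low = j$e_w_low, e_w_high = j$e_w_high,
    intercept_low = j$intercept_low, intercept_high = j$intercept_high,
    r2_low = null2na(j$fit_r2_low), r2_high = null2na(j$fit_r2_high))
}

#' Write calibration series to CSV
#'
#' Long format, both energies stacked: columns energy_kvp,
#' concentration_ug_ml, mean_hu, sd_hu, n_voxels. CT' means are converted
#' back to Hounsfield units (offset removed) and concentrations to ug/ml
#' at this boundary.
#'
#' @param series List with `low`/`high` [calibration_series()].
#' @param path CSV path.
#' @param offset CT' offset to remove.
#' @return Invisibly, `path`.
#' @export
write_calibration_csv <- function(series, path, offset = 1000) {
  one <- function(s) data.frame(
    energy_kvp = attr(s, "energy"),
    concentration_ug_ml = s$concentration * 1000,
    mean_hu = s$mean_ct - offset, sd_hu = s$sd_ct, n_voxels = s$n)
  utils::write.csv(rbind(one(series$low), one(series$high)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file is validated against the known schema: unknown fields anywhere
#' in the tree are a configuration error naming the offending field path.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown config field: ", bad[1], call. = FALSE)
  do.call(pipeline_config, raw)
}
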