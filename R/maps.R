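#' Per-voxel material concentration maps
#'
#' Container for the ground-truth (or recovered) water and gold
#' concentration volumes. All internal concentrations are mg/ml; external
#' interfaces (specs, reports, files) use ug/ml and the factor-1000
#' conversion happens exactly once at those boundaries.
#'
#' @param c_water 3-D array of water concentration, mg/ml; non-negative.
#' @param c_au 3-D array of gold concentration, mg/ml. Ground-truth maps
#'   must be non-negative; recovered maps may carry negative values (noise
#'   can push the per-voxel solution below zero and clipping them would
#'   bias ROI means).
#' @param mask Logical array flagging body (TRUE) vs background voxels.
#' @param voxel_size Voxel spacing (dx, dy, dz) in mm.
#' @param labels Optional integer array of ROI labels (vials or organs),
#'   0 = unlabelled; `label_names` gives the name of label i.
#' @param label_names Optional character vector naming the labels.
#' @param ground_truth Logical; TRUE enforces `c_au >= 0`.
#' @return An object of class `material_maps`.
#' @export
material_maps <- function(c_water, c_au, mask, voxel_size,
                          labels = NULL, label_names = NULL,
                          ground_truth = TRUE) {
  if (!identical(dim(c_water), dim(c_au)) ||
      !identical(dim(c_water), dim(mask)))
    stop("c_water, c_au and mask must share one shape", call. = FALSE)
  if (any(c_water < 0))
    stop("c_water must be non-negative", call. = FALSE)
  if (ground_truth && any(c_au < 0))
    stop("ground-truth c_au must be non-negative", call. = FALSE)
  if (!is.null(labels) && !identical(dim(labels), dim(c_au)))
    stop("labels must share the map shape", call. = FALSE)
  structure(
    list(c_water = c_water, c_au = c_au, mask = mask,
         voxel_size = as.numeric(voxel_size),
         labels = labels, label_names = label_names),
    class = "material_maps")
}

#' @export
print.material_maps <- function(x, ...) {
  d <- dim(x$c_au)
  cat(sprintf("<material_maps> %s voxels @ %s mm, %d body voxels\n",
              paste(d, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), sum(x$mask)))
  if (!is.null(x$label_names))
    cat("  labels:", paste(x$label_names, collapse = ", "), "\n")
  cat(sprintf("  c_au range [%.4g, %.4g] mg/ml\n",
              min(x$c_au), max(x$c_au)))
  invisible(x)
}

# Voxel-centre physical coordinates (mm) of a grid, centred on the volume
# midpoint, one vector per axis.
grid_coords <- function(dim, voxel_size) {
  lapply(1:3, function(a) {
    n <- dim[a]; dx <- voxel_size[a]
    (seq_len(n) - 0.5) * dx - n * dx / 2
  })
}
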