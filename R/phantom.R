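#' Calibration phantom specification
#'
#' A PMMA cylinder carrying vials of gold nanoparticle solution at known
#' concentrations, the physical device used to calibrate the per-energy
#' sensitivity coefficients. Defaults follow the five-vial design with
#' concentrations 250-2000 ug/ml; the geometry (vial size, ring spacing)
#' is a configuration default, as no canonical values exist.
#'
#' @param vial_concentrations Gold concentrations of the vials, ug/ml;
#'   non-negative.
#' @param body_radius Phantom cylinder radius, mm.
#' @param vial_radius Vial radius, mm.
#' @param vial_centres Optional n x 2 matrix of (x, y) vial centres in mm
#'   relative to the phantom axis; default places the vials evenly on a
#'   ring of radius `ring_radius`.
#' @param ring_radius Ring radius for the default vial layout, mm.
#' @param background_material `"pmma"` (water-equivalent concentration
#'   1120 mg/ml, about +120 HU) or `"water"` (1000 mg/ml, 0 HU).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(vial_concentrations = c(250, 500, 1000, 1500, 2000),
                         body_radius = 20, vial_radius = 4,
                         vial_centres = NULL, ring_radius = 12,
                         background_material = c("pmma", "water")) {
  background_material <- match.arg(background_material)
  if (any(vial_concentrations < 0))
    stop("vial concentrations must be non-negative", call. = FALSE)
  n <- length(vial_concentrations)
  if (is.null(vial_centres)) {
    theta <- pi / 2 + 2 * pi * (seq_len(n) - 1) / n
    vial_centres <- cbind(ring_radius * cos(theta), ring_radius * sin(theta))
  }
  vial_centres <- matrix(as.numeric(vial_centres), ncol = 2)
  if (nrow(vial_centres) != n)
    stop("need one centre per vial", call. = FALSE)
  structure(
    list(vial_concentrations = as.numeric(vial_concentrations),
         body_radius = body_radius, vial_radius = vial_radius,
         vial_centres = vial_centres,
         background_material = background_material),
    class = "phantom_spec")
}

# Water-equivalent concentration (mg/ml) of the phantom background.
background_c_water <- function(material) {
  switch(material, pmma = 1120, water = 1000,
         stop("unknown background material: ", material, call. = FALSE))
}

#' Build the digital calibration phantom
#'
#' Voxelizes the phantom on a regular grid: a cylindrical body (axis along
#' z) of background material with axis-aligned cylindrical vials whose
#' voxels carry the vial's gold concentration in water. Vial geometry is
#' validated before painting: every vial must lie strictly inside the body
#' and vials must be pairwise disjoint.
#'
#' @param spec A [phantom_spec()].
#' @param dim Grid dimensions, voxels (length 3).
#' @param voxel_size Voxel spacing (dx, dy, dz), mm.
#' @return A [material_maps()] with ground-truth `c_water`/`c_au`, a body
#'   `mask`, and `labels` marking vial i with integer i.
#' @export
build_phantom <- function(spec, dim = c(96, 96, 16),
                          voxel_size = c(0.5, 0.5, 0.625)) {
  stopifnot(inherits(spec, "phantom_spec"))
  ctr <- spec$vial_centres
  r <- spec$vial_radius
  # geometric validation in continuous coordinates
  if (any(sqrt(rowSums(ctr^2)) + r > spec$body_radius))
    stop("vial outside phantom body", call. = FALSE)
  if (nrow(ctr) > 1) {
    dd <- as.matrix(stats::dist(ctr))
    if (any(dd[upper.tri(dd)] < 2 * r))
      stop("overlapping vials", call. = FALSE)
  }
  co <- grid_coords(dim, voxel_size)
  if (max(abs(co[[1]])) < spec$body_radius ||
      max(abs(co[[2]])) < spec$body_radius)
    stop("grid too small to contain the phantom body", call. = FALSE)
  r2 <- outer(co[[1]]^2, co[[2]]^2, `+`)          # squared in-plane radius
  body2d <- r2 <= spec$body_radius^2
  lab2d <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(ctr))) {
    d2 <- outer((co[[1]] - ctr[i, 1])^2, (co[[2]] - ctr[i, 2])^2, `+`)
    lab2d[d2 <= r^2] <- i
  }
  rep3 <- function(m) array(m, dim)                # extrude along z
  labels <- rep3(lab2d)
  mask <- rep3(body2d)
  c_water <- array(0, dim)
  c_water[mask] <- background_c_water(spec$background_material)
  c_water[labels > 0] <- 1000                      # vials are aqueous
  c_au <- array(0, dim)
  conc_mgml <- spec$vial_concentrations / 1000     # ug/ml -> mg/ml, once
  for (i in seq_along(conc_mgml))
    c_au[labels == i] <- conc_mgml[i]
  material_maps(c_water, c_au, mask, voxel_size, labels = labels,
                label_names = paste0("vial_", seq_along(conc_mgml)))
}
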