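#' Default organ layout of the digital mouse
#'
#' Ellipsoidal organ compartments inside an ellipsoidal torso, sized after
#' a ~20 g nude mouse: liver ~1 cm3, lungs ~0.5 cm3, heart ~80 mm3,
#' kidneys ~50 mm3 each, spleen ~70 mm3, and a subcutaneous flank tumour of
#' ~0.1 cm3 (the tumour volume at which imaging starts). Centres and
#' semi-axes are mm relative to the torso centre.
#'
#' @return Data frame with columns organ, cx, cy, cz, ax, ay, az.
#' @export
mouse_organ_geometry <- function() {
  data.frame(
    organ = c("tumour", "right_kidney", "left_kidney", "lungs",
              "spleen", "heart", "liver"),
    cx = c(-14,   -6,  -6,  18,    2,  18,    6),
    cy = c(  7,  5.5, -5.5,  0, -8.5,   0,    0),
    cz = c(  4,   -3,  -3,   2,    0,  -4,   -2),
    ax = c(2.9,    3,   3, 5.5,    5,   3,  6.5),
    ay = c(2.9,    2,   2,   5,    2, 2.5,    6),
    az = c(2.9,    2,   2, 3.5,    2,   2,  4.5))
}

#' Mouse biodistribution scenario
#'
#' Gold concentrations per organ three hours after tail-vein injection of
#' nanoparticles, with a tumour-uptake multiplier distinguishing the
#' folate-targeted probe from the plain one. Default concentrations follow
#' the usual AuNP biodistribution pattern (reticuloendothelial organs
#' highest); the targeting ratio defaults to 2, the reported
#' targeted-vs-non-targeted contrast.
#'
#' @param organ_concentrations Named numeric vector, ug/ml of gold per
#'   organ in the non-targeted condition. Names must match the geometry's
#'   organ labels.
#' @param targeting_ratio Multiplier applied to the tumour concentration
#'   when the targeted probe is simulated; must be positive.
#' @param tumour_label Name of the tumour organ.
#' @param background_au Gold concentration of unlabelled body tissue
#'   (residual blood pool), ug/ml.
#' @param geometry Organ layout as returned by [mouse_organ_geometry()],
#'   or a precomputed integer label array (see [build_mouse()]).
#' @return An object of class `mouse_scenario`.
#' @export
mouse_scenario <- function(organ_concentrations = c(
                             tumour = 400, right_kidney = 700,
                             left_kidney = 700, lungs = 500,
                             spleen = 1200, heart = 400, liver = 1500),
                           targeting_ratio = 2,
                           tumour_label = "tumour",
                           background_au = 100,
                           geometry = mouse_organ_geometry()) {
  if (any(organ_concentrations < 0) || background_au < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (targeting_ratio <= 0)
    stop("targeting_ratio must be positive", call. = FALSE)
  if (is.null(names(organ_concentrations)))
    stop("organ_concentrations must be named by organ", call. = FALSE)
  structure(
    list(organ_concentrations = organ_concentrations,
         targeting_ratio = targeting_ratio,
         tumour_label = tumour_label,
         background_au = background_au,
         geometry = geometry),
    class = "mouse_scenario")
}

# Torso semi-axes (mm) of the default mouse body ellipsoid.
mouse_body_axes <- function() c(30, 12, 10)

# Paint ellipsoidal organs into an integer label volume; errors if any two
# organs claim the same voxel.
voxelize_organs <- function(geometry, dim, voxel_size) {
  co <- grid_coords(dim, voxel_size)
  labels <- array(0L, dim)
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    u2 <- outer(((co[[1]] - g$cx) / g$ax)^2, ((co[[2]] - g$cy) / g$ay)^2, `+`)
    inside <- outer(u2, ((co[[3]] - g$cz) / g$az)^2, `+`) <= 1
    if (any(labels[inside] != 0L))
      stop("organ geometries overlap: ", g$organ, call. = FALSE)
    labels[inside] <- i
  }
  labels
}

#' Build the digital mouse volume
#'
#' Voxelizes the scenario's organs on a regular grid and assigns each
#' organ's voxels its gold concentration (tumour multiplied by the
#' targeting ratio when `targeted = TRUE`). Unlabelled body voxels carry
#' the background blood-pool concentration; soft tissue is water-equivalent
#' (1000 mg/ml) except the lungs (300 mg/ml, air-filled parenchyma).
#'
#' @param scenario A [mouse_scenario()]. Its `geometry` may be the organ
#'   layout table or a ready-made integer label array whose attribute
#'   `organ_names` names label i.
#' @param dim Grid dimensions, voxels; default spans the torso at 0.25 mm.
#' @param voxel_size Voxel spacing, mm (default 0.25 mm isotropic, chosen
#'   so the 0.1 cm3 tumour contains several thousand voxels).
#' @param targeted Logical; simulate the folate-targeted probe.
#' @return A [material_maps()] with organ `labels`.
#' @export
build_mouse <- function(scenario, dim = c(256, 112, 96),
                        voxel_size = c(0.25, 0.25, 0.25),
                        targeted = FALSE) {
  stopifnot(inherits(scenario, "mouse_scenario"))
  geom <- scenario$geometry
  if (is.array(geom)) {
    labels <- geom
    organ_names <- attr(geom, "organ_names")
    if (is.null(organ_names))
      stop("label-array geometry needs an 'organ_names' attribute",
           call. = FALSE)
    dim <- dim(labels)
  } else {
    organ_names <- geom$organ
    labels <- voxelize_organs(geom, dim, voxel_size)
  }
  conc <- scenario$organ_concentrations
  missing_geom <- setdiff(names(conc), organ_names)
  if (length(missing_geom))
    stop("organ(s) absent from geometry: ",
         paste(missing_geom, collapse = ", "), call. = FALSE)
  for (org in organ_names)
    if (!any(labels == match(org, organ_names)))
      stop("organ has no voxels at this resolution: ", org, call. = FALSE)

  co <- grid_coords(dim, voxel_size)
  ax <- mouse_body_axes()
  u2 <- outer((co[[1]] / ax[1])^2, (co[[2]] / ax[2])^2, `+`)
  mask <- outer(u2, (co[[3]] / ax[3])^2, `+`) <= 1
  mask <- mask | labels > 0

  c_au <- array(0, dim)
  c_au[mask] <- scenario$background_au / 1000      # ug/ml -> mg/ml
  c_water <- array(0, dim)
  c_water[mask] <- 1000
  for (org in names(conc)) {
    i <- match(org, organ_names)
    v <- conc[[org]] / 1000
    if (targeted && identical(org, scenario$tumour_label))
      v <- v * scenario$targeting_ratio
    c_au[labels == i] <- v
    if (identical(org, "lungs")) c_water[labels == i] <- 300
  }
  material_maps(c_water, c_au, mask, voxel_size,
                labels = labels, label_names = organ_names)
}
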