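#' Paired dual-energy CT volumes
#'
#' Holds the co-registered CT volumes acquired at the low and high tube
#' potentials. Volumes are stored internally as shifted CT numbers
#' CT' = HU + `offset` (default offset 1000, so water reads 1000 and air
#' 0), the convention under which the water sensitivity coefficient is
#' nonzero and the two-material system invertible. The offset is removed
#' when volumes are written to NIfTI and restored on read.
#'
#' @param ct_low,ct_high 3-D CT' arrays of identical shape.
#' @param protocol The [scan_protocol()] describing the acquisition.
#' @param offset HU shift applied to the stored volumes.
#' @param mask Optional body mask carried along for downstream statistics.
#' @return An object of class `dual_energy_image`.
#' @export
dual_energy_image <- function(ct_low, ct_high, protocol, offset = 1000,
                              mask = NULL) {
  if (!identical(dim(ct_low), dim(ct_high)))
    stop("low/high volumes must share one shape", call. = FALSE)
  structure(
    list(ct_low = ct_low, ct_high = ct_high, offset = offset,
         protocol = protocol, mask = mask),
    class = "dual_energy_image")
}

#' @export
print.dual_energy_image <- function(x, ...) {
  cat(sprintf("<dual_energy_image> %s voxels, %g/%g kVp, CT' offset %g\n",
              paste(dim(x$ct_low), collapse = "x"),
              x$protocol$energy_low, x$protocol$energy_high, x$offset))
  invisible(x)
}

#' Simulate dual-energy acquisition of a material map
#'
#' The generative counterpart of the per-voxel decomposition: at each
#' energy E the noiseless shifted CT number is the bilinear response
#' \deqn{CT'_E = e_{w,E} C_w + e_{Au,E} C_{Au}}
#' (intercepts play no role in generation; they arise only in calibration
#' fits). Independent Gaussian noise of the protocol's per-energy standard
#' deviation is then added voxelwise, low energy drawn first, using the
#' protocol seed, so a fixed (maps, coeffs, protocol) triple reproduces
#' bit-identical volumes.
#'
#' @param maps Ground-truth [material_maps()].
#' @param coeffs A [sensitivity_matrix()]; its intercepts are ignored here.
#' @param protocol A [scan_protocol()]; `noise_sd` and `seed` drive the
#'   noise draw.
#' @return A [dual_energy_image()] carrying the maps' mask.
#' @export
forward_project <- function(maps, coeffs = default_sensitivity(),
                            protocol = scan_protocol()) {
  stopifnot(inherits(maps, "material_maps"),
            inherits(coeffs, "sensitivity_matrix"))
  if (!is.finite(coeffs$condition_number))
    stop("sensitivity matrix is singular", call. = FALSE)
  d <- dim(maps$c_au)
  ct_low <- coeffs$e_w_low * maps$c_water + coeffs$e_au_low * maps$c_au
  ct_high <- coeffs$e_w_high * maps$c_water + coeffs$e_au_high * maps$c_au
  sd <- protocol$noise_sd
  if (any(sd > 0)) {
    withr::with_seed(protocol$seed, {
      if (sd[1] > 0) ct_low <- ct_low + array(stats::rnorm(prod(d), 0, sd[1]), d)
      if (sd[2] > 0) ct_high <- ct_high + array(stats::rnorm(prod(d), 0, sd[2]), d)
    })
  }
  dual_energy_image(ct_low, ct_high, protocol, mask = maps$mask)
}
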