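# Shared fixtures: a small calibration phantom (coarse 1 mm grid keeps the
# unit tests fast; the acceptance suite runs the full-resolution phantom)
# and an exactly linear calibration series.

tiny_phantom <- function(noise_sd = 0, seed = 1L,
                         spec = phantom_spec(),
                         coeffs = default_sensitivity()) {
  maps <- build_phantom(spec, dim = c(48, 48, 8), voxel_size = c(1, 1, 1))
  proto <- scan_protocol(voxel_size = c(1, 1, 1), noise_sd = noise_sd,
                         seed = seed)
  list(spec = spec, maps = maps, coeffs = coeffs, protocol = proto,
       image = forward_project(maps, coeffs, proto))
}

exact_series <- function(slope, intercept = 1000, energy = 80,
                         conc = c(0.25, 0.5, 1, 1.5, 2), n = 100) {
  calibration_series(conc, intercept + slope * conc,
                     sd_ct = rep(1, length(conc)),
                     n = rep(n, length(conc)), energy = energy)
}

# Uniform-concentration block, the simplest decomposition target.
uniform_maps <- function(dim, c_water = 1000, c_au = 1,
                         voxel_size = c(1, 1, 1)) {
  material_maps(array(c_water, dim), array(c_au, dim),
                array(TRUE, dim), voxel_size)
}
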