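test_that("per-voxel inversion solves hand-checked systems", {
  # identity matrix: concentrations are the CT pair itself
  id <- sensitivity_matrix(e_au_low = 0, e_au_high = 1,
                           e_w_low = 1, e_w_high = 0)
  sol <- decompose_voxel(3, 7, id)
  expect_equal(sol$c_water, 3)
  expect_equal(sol$c_au, 7)
  # rows (1, 5) and (1, 7), CT' = (1010, 1014): solution (1000, 2)
  sol <- decompose_voxel(1010, 1014, sensitivity_matrix(5, 7))
  expect_equal(sol$c_water, 1000)
  expect_equal(sol$c_au, 2)
})

test_that("singular or ill-conditioned systems are hard errors", {
  expect_error(decompose_voxel(1, 2, sensitivity_matrix(6, 6)), "singular")
  near <- sensitivity_matrix(22, 22 + 1e-9)
  expect_error(decompose_voxel(1, 2, near, condition_cap = 1e6),
               "condition")
})

test_that("analytic inverse matches a generic linear solve on random systems", {
  set.seed(2024)
  worst <- 0
  for (k in 1:1000) {
    e <- runif(4, 0.5, 30)
    fit <- sensitivity_matrix(e_au_low = e[2], e_au_high = e[4],
                              e_w_low = e[1], e_w_high = e[3])
    if (!is.finite(fit$condition_number) || fit$condition_number > 1e4) next
    ct <- runif(2, 900, 1100)
    mine <- decompose_voxel(ct[1], ct[2], fit)
    M <- rbind(c(e[1], e[2]), c(e[3], e[4]))
    oracle <- solve(M, ct)
    rel <- abs(c(mine$c_water, mine$c_au) - oracle) /
      pmax(abs(oracle), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-9)
})

test_that("noiseless volume decomposition is the exact inverse of simulation", {
  fx <- tiny_phantom(noise_sd = 0)
  ser <- measure_vials(fx$image, fx$maps$labels, fx$spec$vial_concentrations)
  fit <- fit_sensitivity(ser$low, ser$high)
  dec <- decompose_volume(fx$image, fit)
  expect_lt(max(abs(dec$maps$c_au - fx$maps$c_au)), 1e-6)
  expect_lt(max(abs(dec$maps$c_water - fx$maps$c_water)), 1e-6)
  expect_equal(dec$negatives_fraction, 0)
  # the same holds when decomposing with the a-priori generating matrix
  dec2 <- decompose_volume(fx$image, fx$coeffs)
  expect_lt(max(abs(dec2$maps$c_au - fx$maps$c_au)), 1e-6)
})

test_that("pure-water noisy volume decomposes to zero gold on average", {
  dim <- c(48, 48, 24)
  maps <- uniform_maps(dim, c_water = 1000, c_au = 0)
  proto <- scan_protocol(noise_sd = 10, seed = 9, voxel_size = c(1, 1, 1))
  fit <- default_sensitivity()
  dec <- decompose_volume(forward_project(maps, fit, proto), fit)
  n <- prod(dim)
  sd_au <- 10 * noise_amplification(fit)
  expect_lt(abs(mean(dec$maps$c_au)), 3 * sd_au / sqrt(n))
  expect_gt(dec$negatives_fraction, 0.3)   # zero-mean noise: ~half negative
})

test_that("empirical decomposition noise matches the closed-form propagation", {
  dim <- c(64, 64, 32)                     # > 1e5 voxels
  maps <- uniform_maps(dim, c_au = 1)
  fit <- default_sensitivity()
  proto <- scan_protocol(noise_sd = 10, seed = 17, voxel_size = c(1, 1, 1))
  dec <- decompose_volume(forward_project(maps, fit, proto), fit)
  predicted <- 10 * noise_amplification(fit)    # sigma * ||row2 Minv||
  expect_equal(sd(dec$maps$c_au), predicted, tolerance = 0.05)
  # closed form for the water convention: sigma * sqrt(2) / |slope gap|
  expect_equal(predicted, 10 * sqrt(2) / 5, tolerance = 1e-12)
})

test_that("ROI-mean error shrinks with voxel count (seed-averaged)", {
  fit <- default_sensitivity()
  mean_err <- function(dim, seeds) {
    mean(vapply(seeds, function(s) {
      proto <- scan_protocol(noise_sd = 10, seed = s,
                             voxel_size = c(1, 1, 1))
      dec <- decompose_volume(
        forward_project(uniform_maps(dim, c_au = 1), fit, proto), fit)
      abs(mean(dec$maps$c_au) - 1)
    }, numeric(1)))
  }
  expect_lt(mean_err(c(40, 40, 40), 1:5), mean_err(c(10, 10, 10), 1:5))
})

test_that("clipping floors the map at zero without touching the negatives record", {
  maps <- uniform_maps(c(24, 24, 24), c_au = 0.05)
  fit <- default_sensitivity()
  proto <- scan_protocol(noise_sd = 10, seed = 4, voxel_size = c(1, 1, 1))
  img <- forward_project(maps, fit, proto)
  raw <- decompose_volume(img, fit, clip_negative = FALSE)
  clip <- decompose_volume(img, fit, clip_negative = TRUE)
  expect_gt(raw$negatives_fraction, 0)
  expect_lt(min(raw$maps$c_au), 0)
  expect_equal(min(clip$maps$c_au), 0)
  expect_equal(clip$negatives_fraction, raw$negatives_fraction)
})

test_that("background voxels are zeroed and excluded from statistics", {
  fx <- tiny_phantom(noise_sd = 10, seed = 6)
  dec <- decompose_volume(fx$image, fx$coeffs)
  expect_true(all(dec$maps$c_au[!fx$maps$mask] == 0))
  bad_mask <- array(TRUE, dim(fx$image$ct_low) + c(0, 0, 1))
  expect_error(decompose_volume(fx$image, fx$coeffs, mask = bad_mask),
               "mask")
})
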