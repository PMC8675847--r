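test_that("vial ROI measurement returns exact statistics on noiseless data", {
  fx <- tiny_phantom(noise_sd = 0)
  ser <- measure_vials(fx$image, fx$maps$labels,
                       fx$spec$vial_concentrations)
  expect_equal(ser$low$concentration, c(0.25, 0.5, 1, 1.5, 2))
  expect_equal(attr(ser$low, "energy"), 80)
  expect_equal(attr(ser$high, "energy"), 140)
  # noiseless uniform vials: mean = 1000 + slope * c, sd = 0
  expect_equal(ser$low$mean_ct, 1000 + 22 * ser$low$concentration)
  expect_equal(ser$high$mean_ct, 1000 + 27 * ser$high$concentration)
  expect_true(all(ser$low$sd_ct == 0) && all(ser$high$sd_ct == 0))
  expect_true(all(ser$low$n >= 1))
})

test_that("vial measurement validates masks and grids", {
  fx <- tiny_phantom(noise_sd = 0)
  expect_error(measure_vials(fx$image, fx$maps$labels, c(250, 500, 1000, 1500, 2000, 9999)),
               "empty vial mask")
  bad <- array(0L, dim(fx$image$ct_low) + c(1, 0, 0))
  expect_error(measure_vials(fx$image, bad, 250), "grid")
})

test_that("OLS reproduces exactly collinear series to numerical precision", {
  lo <- exact_series(slope = 6, intercept = 1000, energy = 80)
  hi <- exact_series(slope = 9, intercept = 1000, energy = 140)
  fit <- fit_sensitivity(lo, hi)
  expect_equal(fit$e_au_low, 6, tolerance = 1e-12)
  expect_equal(fit$e_au_high, 9, tolerance = 1e-12)
  expect_equal(fit$intercept_low, 1000, tolerance = 1e-9)
  expect_equal(fit$fit_r2_low, 1)
  expect_equal(fit$fit_r2_high, 1)
  expect_equal(fit$e_w_low, 1)
})

test_that("slope is invariant to a constant CT shift, which moves the intercept", {
  lo <- exact_series(slope = 6)
  shifted <- lo
  shifted$mean_ct <- shifted$mean_ct + 57
  f1 <- fit_sensitivity(lo, exact_series(9, energy = 140))
  f2 <- fit_sensitivity(shifted, exact_series(9, energy = 140))
  expect_equal(f2$e_au_low, f1$e_au_low)
  expect_equal(f2$intercept_low, f1$intercept_low + 57)
})

test_that("degenerate and pathological designs are flagged", {
  one_conc <- calibration_series(c(1, 1, 1), c(1022, 1023, 1021),
                                 rep(1, 3), rep(10, 3), 80)
  expect_error(fit_sensitivity(one_conc, exact_series(9, energy = 140)),
               "degenerate")
  # equal slopes at both energies -> singular, infinite condition number
  fit <- fit_sensitivity(exact_series(6), exact_series(6, energy = 140))
  expect_false(is.finite(fit$condition_number))
  neg <- exact_series(-2)
  expect_warning(fit_sensitivity(neg, exact_series(9, energy = 140)),
                 "negative")
})

test_that("condition number grows as the energy slopes converge", {
  gaps <- c(8, 4, 2, 1, 0.5, 0.25)
  conds <- vapply(gaps, function(g)
    sensitivity_matrix(22, 22 + g)$condition_number, numeric(1))
  expect_true(all(diff(conds) > 0))
  expect_true(all(conds >= 1))
})

test_that("noisy calibration recovers the generating slope within 3 SE", {
  # five vials, 500 voxels each, per-voxel HU' noise sd 10
  slope_true <- c(low = 22, high = 27)
  conc <- c(0.25, 0.5, 1, 1.5, 2)
  mk <- function(slope, energy, seed) {
    withr::with_seed(seed, {
      rows <- vapply(conc, function(cc) {
        v <- 1000 + slope * cc + rnorm(500, 0, 10)
        c(mean(v), sd(v))
      }, numeric(2))
    })
    calibration_series(conc, rows[1, ], rows[2, ], rep(500, 5), energy)
  }
  fit <- fit_sensitivity(mk(22, 80, 11), mk(27, 140, 12))
  expect_lt(abs(fit$e_au_low - 22), 3 * fit$slope_se[["low"]])
  expect_lt(abs(fit$e_au_high - 27), 3 * fit$slope_se[["high"]])
  # weighted fit accepts the same series and stays close
  fitw <- fit_sensitivity(mk(22, 80, 11), mk(27, 140, 12), weighted = TRUE)
  expect_equal(fitw$e_au_low, fit$e_au_low, tolerance = 0.1)
})

test_that("calibration validation round-trips a noiseless phantom exactly", {
  fx <- tiny_phantom(noise_sd = 0)
  ser <- measure_vials(fx$image, fx$maps$labels, fx$spec$vial_concentrations)
  fit <- fit_sensitivity(ser$low, ser$high)
  val <- validate_calibration(fit, ser, fx$spec$vial_concentrations)
  expect_equal(val$per_vial$relative_error, rep(0, 5), tolerance = 1e-10)
  expect_equal(val$correlation, 1, tolerance = 1e-12)
  expect_error(validate_calibration(fit, ser, c(250, 500)), "length")
})

test_that("noisy-phantom validation error stays within its propagated bound", {
  fx <- tiny_phantom(noise_sd = 10, seed = 3)
  ser <- measure_vials(fx$image, fx$maps$labels, fx$spec$vial_concentrations)
  fit <- fit_sensitivity(ser$low, ser$high)
  val <- validate_calibration(fit, ser, fx$spec$vial_concentrations)
  # per-vial recovered-concentration sd from first principles: ROI-mean HU
  # noise 10/sqrt(n), amplified by the gold channel of the inverse system;
  # 3x the mean relative sd bounds the mean absolute relative error
  amp <- noise_amplification(default_sensitivity())
  rel_sd <- (10 / sqrt(ser$low$n)) * amp /
    (fx$spec$vial_concentrations / 1000)
  expect_lt(val$mean_abs_relative_error, 3 * mean(rel_sd))
  # correlation floor: attenuation from the propagated per-vial error sd,
  # with the error inflated 2x as margin
  sd_err <- mean(10 / sqrt(ser$low$n)) * amp
  sd_truth <- sd(fx$spec$vial_concentrations / 1000)
  expect_gt(val$correlation,
            sd_truth / sqrt(sd_truth^2 + (2 * sd_err)^2))
})
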