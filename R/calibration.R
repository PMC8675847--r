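#' Vial calibration series
#'
#' Per-energy summary of the calibration phantom: one row per vial with
#' its nominal gold concentration and the mean/spread of shifted CT
#' numbers over the vial ROI.
#'
#' @param concentration Gold concentrations, mg/ml.
#' @param mean_ct Mean CT' over each vial ROI, HU'.
#' @param sd_ct Standard deviation of CT' over each vial ROI.
#' @param n Voxels per ROI.
#' @param energy kVp label of the series.
#' @return A data frame of class `calibration_series` with attribute
#'   `energy`.
#' @export
calibration_series <- function(concentration, mean_ct, sd_ct, n, energy) {
  if (any(n < 1)) stop("each point needs >= 1 voxel", call. = FALSE)
  if (any(sd_ct < 0)) stop("sd must be non-negative", call. = FALSE)
  out <- data.frame(concentration = concentration, mean_ct = mean_ct,
                    sd_ct = sd_ct, n = as.integer(n))
  attr(out, "energy") <- energy
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Measure vial ROIs of a dual-energy phantom image
#'
#' Computes, per vial and per energy, the mean and standard deviation of
#' CT' over the vial's voxels, paired with the vial's nominal gold
#' concentration.
#'
#' @param image A [dual_energy_image()] of the phantom.
#' @param vial_labels Integer label volume (vial i labelled i) on the image
#'   grid, e.g. the `labels` of [build_phantom()].
#' @param concentrations_ug_ml Nominal vial concentrations, ug/ml, in label
#'   order (converted to mg/ml here, the single unit-conversion point).
#' @return List with elements `low` and `high`, each a
#'   [calibration_series()].
#' @export
measure_vials <- function(image, vial_labels, concentrations_ug_ml) {
  stopifnot(inherits(image, "dual_energy_image"))
  if (!identical(dim(vial_labels), dim(image$ct_low)))
    stop("vial labels do not match the image grid", call. = FALSE)
  conc <- concentrations_ug_ml / 1000
  one_energy <- function(vol, energy) {
    stats_per_vial <- lapply(seq_along(conc), function(i) {
      v <- vol[vial_labels == i]
      if (length(v) == 0)
        stop("empty vial mask: vial ", i, call. = FALSE)
      c(mean(v), stats::sd(v), length(v))
    })
    m <- do.call(rbind, stats_per_vial)
    m[is.na(m[, 2]), 2] <- 0                       # single-voxel ROI
    calibration_series(conc, m[, 1], m[, 2], m[, 3], energy)
  }
  list(low = one_energy(image$ct_low, image$protocol$energy_low),
       high = one_energy(image$ct_high, image$protocol$energy_high))
}

#' Fit per-energy sensitivity coefficients from vial series
#'
#' Ordinary least squares of mean CT' against gold concentration, one line
#' per energy: the slope is the gold sensitivity coefficient e_Au,E
#' (HU' per mg/ml) and the intercept absorbs the vials' water baseline.
#' The water coefficients are fixed at the convention value (1 HU' per
#' mg/ml) unless overridden by a water-dilution measurement. An optional
#' inverse-variance weighting (1/sd^2, scaled by ROI size) refines the
#' plain fit when vial spreads differ.
#'
#' @param series_low,series_high [calibration_series()] at the two
#'   energies; each needs >= 2 distinct concentrations.
#' @param weighted Use weights n/sd^2 instead of unweighted OLS.
#' @param e_w Water coefficient(s); length 1 or 2 (low, high).
#' @return A [sensitivity_matrix()] with fitted slopes, intercepts and
#'   per-energy r-squared.
#' @export
fit_sensitivity <- function(series_low, series_high, weighted = FALSE,
                            e_w = 1) {
  e_w <- rep_len(e_w, 2L)
  fit_one <- function(s) {
    if (length(unique(s$concentration)) < 2)
      stop("degenerate design: need >= 2 distinct concentrations",
           call. = FALSE)
    w <- if (weighted) {
      if (any(s$sd_ct <= 0))
        stop("weighted fit needs positive sd for every vial", call. = FALSE)
      s$n / s$sd_ct^2
    } else NULL
    fm <- stats::lm(mean_ct ~ concentration, data = s, weights = w)
    slope <- unname(stats::coef(fm)[2])
    if (slope < 0)
      warning("negative fitted gold sensitivity at ", attr(s, "energy"),
              " kVp", call. = FALSE)
    sm <- suppressWarnings(summary(fm))   # noiseless series fit exactly
    c(intercept = unname(stats::coef(fm)[1]), slope = slope,
      r2 = sm$r.squared, se = sm$coefficients[2, 2])
  }
  lo <- fit_one(series_low); hi <- fit_one(series_high)
  out <- sensitivity_matrix(
    e_au_low = lo[["slope"]], e_au_high = hi[["slope"]],
    e_w_low = e_w[1], e_w_high = e_w[2],
    intercept_low = lo[["intercept"]], intercept_high = hi[["intercept"]],
    r2_low = lo[["r2"]], r2_high = hi[["r2"]])
  out$slope_se <- c(low = lo[["se"]], high = hi[["se"]])
  out
}

#' Validate a calibration by back-predicting vial concentrations
#'
#' Feeds each vial's mean CT' pair through the fitted decomposition and
#' compares the recovered gold concentration with an independent reference
#' list (the role ICP-MS plays for a physical phantom). Reports per-vial
#' relative error plus the overall Pearson correlation and mean absolute
#' relative error.
#'
#' @param fit A [sensitivity_matrix()].
#' @param series List with `low`/`high` [calibration_series()] (matched
#'   rows).
#' @param reference_ug_ml Reference concentrations, ug/ml, one per vial.
#' @param condition_cap Condition-number cap for the inversion.
#' @return List with `per_vial` data frame (reference_ug_ml,
#'   recovered_ug_ml, relative_error), `correlation`, and
#'   `mean_abs_relative_error`.
#' @export
validate_calibration <- function(fit, series, reference_ug_ml,
                                 condition_cap = 1e6) {
  s_lo <- series$low; s_hi <- series$high
  if (nrow(s_lo) != length(reference_ug_ml))
    stop("reference list length does not match the series", call. = FALSE)
  sol <- decompose_voxel(s_lo$mean_ct, s_hi$mean_ct, fit, condition_cap)
  rec <- sol$c_au * 1000
  rel <- ifelse(reference_ug_ml > 0,
                (rec - reference_ug_ml) / reference_ug_ml, NA_real_)
  corr <- if (stats::sd(reference_ug_ml) > 0 && stats::sd(rec) > 0)
    stats::cor(rec, reference_ug_ml) else NA_real_
  list(per_vial = data.frame(reference_ug_ml = reference_ug_ml,
                             recovered_ug_ml = rec,
                             relative_error = rel),
       correlation = corr,
       mean_abs_relative_error = mean(abs(rel), na.rm = TRUE))
}
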