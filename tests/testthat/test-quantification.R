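test_that("uniform organ quantifies to its concentration in ug/ml", {
  dim <- c(12, 12, 6)
  labels <- array(0L, dim); labels[4:9, 4:9, 2:5] <- 1L
  maps <- material_maps(array(1000, dim), array(0, dim) + 1 * (labels == 1),
                        array(TRUE, dim), c(1, 1, 1),
                        labels = labels, label_names = "tumour")
  q <- quantify_rois(maps)
  expect_equal(q$mean_ug_ml, 1000)
  expect_equal(q$sd_ug_ml, 0)
  expect_equal(q$n_voxels, sum(labels == 1))
})

test_that("a simulated mouse yields one row per organ of the panel", {
  sc <- mouse_scenario()
  maps <- build_mouse(sc, dim = c(64, 28, 24), voxel_size = c(1, 1, 1))
  q <- quantify_rois(maps)
  expect_equal(nrow(q), 7)
  expect_setequal(q$organ, c("tumour", "right_kidney", "left_kidney",
                             "lungs", "spleen", "heart", "liver"))
  # noiseless ground truth: every organ mean equals the scenario value
  expect_equal(q$mean_ug_ml[match(names(sc$organ_concentrations), q$organ)],
               unname(sc$organ_concentrations))
})

test_that("missing organs and label mismatches are errors", {
  dim <- c(8, 8, 4)
  maps <- material_maps(array(1000, dim), array(0, dim), array(TRUE, dim),
                        c(1, 1, 1), labels = array(0L, dim),
                        label_names = "tumour")
  expect_error(quantify_rois(maps), "empty organ")
  maps$labels <- NULL
  expect_error(quantify_rois(maps), "required")
})

test_that("ROI mean is invariant to splitting and voxel order", {
  dim <- c(16, 16, 8)
  set.seed(31)
  c_au <- array(rnorm(prod(dim), 1, 0.3), dim)
  labels <- array(0L, dim); labels[3:14, 3:14, 2:7] <- 1L
  maps <- material_maps(array(1000, dim), abs(c_au), array(TRUE, dim),
                        c(1, 1, 1), labels = labels, label_names = "organ")
  whole <- quantify_rois(maps)
  # split the organ into two sub-masks; the size-weighted mean recombines
  sub <- labels
  sub[labels == 1L & seq_along(labels) %% 2 == 0] <- 2L
  maps$labels <- sub; maps$label_names <- c("a", "b")
  parts <- quantify_rois(maps)
  recombined <- sum(parts$mean_ug_ml * parts$n_voxels) / sum(parts$n_voxels)
  expect_equal(recombined, whole$mean_ug_ml)
})

test_that("reference comparison reports identity and degenerate cases", {
  dect <- data.frame(organ = c("liver", "tumour"), n_voxels = c(10, 10),
                     mean_ug_ml = c(1500, 400), sd_ug_ml = c(0, 0))
  rep1 <- compare_with_reference(dect, c(liver = 1500, tumour = 400))
  expect_equal(rep1$rows$relative_error, c(0, 0))
  expect_equal(rep1$summary$correlation, 1)
  expect_equal(rep1$summary$mean_bias_ug_ml, 0)
  # zero reference: relative error undefined, absolute difference reported
  dect0 <- data.frame(organ = "liver", n_voxels = 5, mean_ug_ml = 0,
                      sd_ug_ml = 0)
  rep0 <- compare_with_reference(dect0, c(liver = 0))
  expect_true(is.na(rep0$rows$relative_error))
  expect_equal(rep0$rows$abs_difference_ug_ml, 0)
  expect_true(is.na(rep0$summary$correlation))
  expect_equal(rep0$summary$mean_bias_ug_ml, 0)
  expect_error(compare_with_reference(dect, c(liver = 1, spleen = 2)),
               "match")
})

test_that("targeting contrast recovers the scenario ratio exactly when noiseless", {
  sc <- mouse_scenario(targeting_ratio = 2)
  dm <- c(64, 28, 24); vx <- c(1, 1, 1)
  q_nt <- quantify_rois(build_mouse(sc, dm, vx, targeted = FALSE))
  q_t <- quantify_rois(build_mouse(sc, dm, vx, targeted = TRUE))
  expect_equal(targeting_contrast(q_t, q_nt), 2)
  expect_equal(targeting_contrast(q_nt, q_nt), 1)
})

test_that("targeting contrast validates its inputs", {
  q <- data.frame(organ = "liver", n_voxels = 1, mean_ug_ml = 10,
                  sd_ug_ml = 0)
  expect_error(targeting_contrast(q, q), "tumour")
  qz <- data.frame(organ = "tumour", n_voxels = 1, mean_ug_ml = 0,
                   sd_ug_ml = 0)
  qt <- data.frame(organ = "tumour", n_voxels = 1, mean_ug_ml = 5,
                   sd_ug_ml = 0)
  expect_error(targeting_contrast(qt, qz), "zero")
})

test_that("organ relative error shrinks with ROI size at fixed noise", {
  fit <- default_sensitivity()
  err_at <- function(dim, seeds) {
    mean(vapply(seeds, function(s) {
      maps <- uniform_maps(dim, c_au = 0.5)
      proto <- scan_protocol(noise_sd = 10, seed = s,
                             voxel_size = c(1, 1, 1))
      dec <- decompose_volume(forward_project(maps, fit, proto), fit)
      labels <- array(1L, dim)
      q <- quantify_rois(dec$maps, labels, "organ")
      abs(q$mean_ug_ml - 500) / 500
    }, numeric(1)))
  }
  expect_lt(err_at(c(32, 32, 32), 1:5), err_at(c(8, 8, 8), 1:5))
})
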