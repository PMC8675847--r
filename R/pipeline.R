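#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full simulate ->
#' calibrate -> decompose -> quantify run. Unknown fields anywhere in the
#' tree raise a configuration error naming the field, so typos cannot
#' silently fall back to defaults.
#'
#' @param protocol List of [scan_protocol()] arguments.
#' @param phantom List of [phantom_spec()] arguments plus optional `dim`
#'   and `voxel_size` grid fields.
#' @param mouse List of [mouse_scenario()] arguments plus optional `dim`,
#'   `voxel_size` and `noise_sd` (per-energy HU noise of the in vivo scan,
#'   defaulting to the protocol's).
#' @param options List: `clip_negative`, `weighted`, `condition_cap`,
#'   `icpms_noise_cv` (multiplicative lognormal CV perturbing the
#'   reference concentrations; 0 disables, the default).
#' @param seed Master seed; per-stage substreams are derived from it
#'   (phantom scan `seed`, non-targeted mouse `seed + 1`, targeted mouse
#'   `seed + 2`, reference perturbation `seed + 3`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = list(), phantom = list(),
                            mouse = list(), options = list(), seed = 1L) {
  check_fields <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown config field: ", where, ".", bad[1], call. = FALSE)
    x
  }
  protocol <- check_fields(protocol, names(formals(scan_protocol)),
                           "protocol")
  phantom <- check_fields(phantom,
                          c(names(formals(phantom_spec)), "dim", "voxel_size"),
                          "phantom")
  mouse <- check_fields(mouse,
                        c(names(formals(mouse_scenario)), "dim",
                          "voxel_size", "noise_sd"),
                        "mouse")
  options <- check_fields(options,
                          c("clip_negative", "weighted", "condition_cap",
                            "icpms_noise_cv"),
                          "options")
  opts <- utils::modifyList(
    list(clip_negative = FALSE, weighted = FALSE, condition_cap = 1e6,
         icpms_noise_cv = 0), options)
  structure(list(protocol = protocol, phantom = phantom, mouse = mouse,
                 options = opts, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

# Multiplicative lognormal perturbation emulating reference-assay
# (ICP-MS) measurement error; mean-preserving, cv = coefficient of
# variation. cv = 0 returns the input unchanged.
perturb_reference <- function(reference_ug_ml, cv, seed) {
  if (cv <= 0) return(reference_ug_ml)
  s <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, reference_ug_ml *
                     stats::rlnorm(length(reference_ug_ml), -s^2 / 2, s))
}

#' Run the full quantification pipeline
#'
#' Executes the four stages in order — simulate (phantom and both mouse
#' conditions), calibrate, decompose, quantify — writing every artifact
#' under `out_dir` and a `manifest.json` recording the package version,
#' master seed, configuration hash, completed stages, and an MD5 checksum
#' for every output file. Reruns with identical configuration and seed are
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; contents overwritten).
#' @param mouse_dim,mouse_voxel Grid used for the mouse volumes unless the
#'   config sets its own (the default keeps the demo run light).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir,
                         mouse_dim = c(128, 56, 48),
                         mouse_voxel = c(0.5, 0.5, 0.5)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  proto_args <- config$protocol
  proto_args$seed <- config$seed
  protocol <- do.call(scan_protocol, proto_args)

  ## -- simulate ----------------------------------------------------------
  ph_args <- config$phantom
  ph_dim <- ph_args$dim %||% c(96, 96, 16)
  ph_vox <- ph_args$voxel_size %||% c(0.5, 0.5, 0.625)
  ph_args$dim <- ph_args$voxel_size <- NULL
  spec <- do.call(phantom_spec, ph_args)
  ph_maps <- build_phantom(spec, dim = ph_dim, voxel_size = ph_vox)
  ph_proto <- protocol
  ph_proto$voxel_size <- ph_vox
  ph_img <- forward_project(ph_maps, default_sensitivity(), ph_proto)

  m_args <- config$mouse
  m_dim <- m_args$dim %||% mouse_dim
  m_vox <- m_args$voxel_size %||% mouse_voxel
  m_sd <- m_args$noise_sd %||% protocol$noise_sd
  m_args$dim <- m_args$voxel_size <- m_args$noise_sd <- NULL
  scenario <- do.call(mouse_scenario, m_args)
  maps_nt <- build_mouse(scenario, dim = m_dim, voxel_size = m_vox,
                         targeted = FALSE)
  maps_t <- build_mouse(scenario, dim = m_dim, voxel_size = m_vox,
                        targeted = TRUE)
  m_proto <- protocol
  m_proto$voxel_size <- m_vox
  m_proto$noise_sd <- rep_len(as.numeric(m_sd), 2L)
  m_proto$seed <- config$seed + 1L
  img_nt <- forward_project(maps_nt, default_sensitivity(), m_proto)
  m_proto$seed <- config$seed + 2L
  img_t <- forward_project(maps_t, default_sensitivity(), m_proto)

  add(write_dual_energy(ph_img, file.path(out_dir, "sim", "phantom")))
  add(write_material_maps(ph_maps, file.path(out_dir, "sim", "phantom_truth")))
  add(write_dual_energy(img_nt, file.path(out_dir, "sim", "mouse_nontargeted")))
  add(write_dual_energy(img_t, file.path(out_dir, "sim", "mouse_targeted")))
  add(write_material_maps(maps_nt, file.path(out_dir, "sim", "mouse_truth_nontargeted")))
  add(write_material_maps(maps_t, file.path(out_dir, "sim", "mouse_truth_targeted")))
  stages <- c(stages, "simulate")

  ## -- calibrate ---------------------------------------------------------
  series <- measure_vials(ph_img, ph_maps$labels, spec$vial_concentrations)
  fit <- fit_sensitivity(series$low, series$high,
                         weighted = config$options$weighted)
  val <- validate_calibration(fit, series, spec$vial_concentrations,
                              condition_cap = config$options$condition_cap)
  dir.create(file.path(out_dir, "calibration"), showWarnings = FALSE)
  add(write_sensitivity(fit, file.path(out_dir, "calibration", "fit.json")))
  add(write_calibration_csv(series,
                            file.path(out_dir, "calibration", "series.csv")))
  vf <- file.path(out_dir, "calibration", "validation.csv")
  utils::write.csv(val$per_vial, vf, row.names = FALSE)
  add(vf)
  stages <- c(stages, "calibrate")

  ## -- decompose ---------------------------------------------------------
  cap <- config$options$condition_cap
  clip <- config$options$clip_negative
  dec_ph <- decompose_volume(ph_img, fit, clip_negative = clip,
                             condition_cap = cap)
  dec_nt <- decompose_volume(img_nt, fit, clip_negative = clip,
                             condition_cap = cap)
  dec_t <- decompose_volume(img_t, fit, clip_negative = clip,
                            condition_cap = cap)
  add(write_material_maps(dec_ph$maps, file.path(out_dir, "decomposed", "phantom")))
  add(write_material_maps(dec_nt$maps, file.path(out_dir, "decomposed", "mouse_nontargeted")))
  add(write_material_maps(dec_t$maps, file.path(out_dir, "decomposed", "mouse_targeted")))
  sf <- file.path(out_dir, "decomposed", "summary.json")
  jsonlite::write_json(
    list(phantom = dec_ph$negatives_fraction,
         mouse_nontargeted = dec_nt$negatives_fraction,
         mouse_targeted = dec_t$negatives_fraction,
         condition_number = fit$condition_number,
         clipped = clip),
    sf, auto_unbox = TRUE, digits = NA)
  add(sf)
  stages <- c(stages, "decompose")

  ## -- quantify ----------------------------------------------------------
  ref_nt <- scenario$organ_concentrations
  ref_t <- ref_nt
  ref_t[scenario$tumour_label] <-
    ref_t[scenario$tumour_label] * scenario$targeting_ratio
  cv <- config$options$icpms_noise_cv
  ref_nt <- stats::setNames(perturb_reference(unname(ref_nt), cv,
                                              config$seed + 3L),
                            names(ref_nt))
  ref_t <- stats::setNames(perturb_reference(unname(ref_t), cv,
                                             config$seed + 3L),
                           names(ref_t))
  q_nt <- quantify_rois(dec_nt$maps, maps_nt$labels, maps_nt$label_names)
  q_t <- quantify_rois(dec_t$maps, maps_t$labels, maps_t$label_names)
  rep_nt <- compare_with_reference(q_nt, ref_nt)
  rep_t <- compare_with_reference(q_t, ref_t)
  ratio <- targeting_contrast(rep_t, rep_nt,
                              tumour_label = scenario$tumour_label)
  dir.create(file.path(out_dir, "quantification"), showWarnings = FALSE)
  for (nm in c("nontargeted", "targeted")) {
    r <- if (nm == "targeted") rep_t else rep_nt
    f <- file.path(out_dir, "quantification", paste0("roi_", nm, ".csv"))
    utils::write.csv(r$rows, f, row.names = FALSE)
    add(f)
  }
  qf <- file.path(out_dir, "quantification", "summary.json")
  jsonlite::write_json(
    list(nontargeted = rep_nt$summary, targeted = rep_t$summary,
         tumour_uptake_ratio = ratio),
    qf, auto_unbox = TRUE, digits = NA, na = "null")
  add(qf)
  stages <- c(stages, "quantify")

  ## -- manifest ----------------------------------------------------------
  files <- unique(files)
  manifest <- list(
    package = "dectquant",
    version = as.character(utils::packageVersion("dectquant")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    files = lapply(files, function(f) list(
      path = sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", out_dir),
                        "/?"), "", f),
      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
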