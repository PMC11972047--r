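#' Study configuration
#'
#' Bundles every knob of the in-silico study; the defaults reproduce the
#' canonical setup: 10 cm water cube, 2 mm voxels, 2 cm Dotarem target at
#' 0.5 mmol/mL, 4 Gy prescription, 3 mm spot lattice, 2 mm WE layer spacing,
#' 8.7 cm scoring sphere, 2 mm displacement steps to +-10 mm.
#'
#' @param target_material `"dotarem"` or `"water"` (control).
#' @param gd_concentration_mmol_ml Gd concentration in the target.
#' @param prescription_Gy Uniform target prescription.
#' @param spacing_mm Lateral spot spacing.
#' @param layer_spacing_we_mm Energy-layer WE spacing.
#' @param extent_cm,voxel_mm,target_cm Phantom geometry.
#' @param models An `engine_models` bundle.
#' @param steps_transverse_mm,steps_longitudinal_mm Scenario step sets.
#' @param seed Top-level seed (all substreams derive from it).
#' @param channels Emission channels to tally.
#' @return Object of class `study_config`.
#' @export
study_config <- function(target_material = c("dotarem", "water"),
                         gd_concentration_mmol_ml = 0.5,
                         prescription_Gy = 4,
                         spacing_mm = 3, layer_spacing_we_mm = 2,
                         extent_cm = 10, voxel_mm = 2, target_cm = 2,
                         models = engine_models(),
                         steps_transverse_mm = seq(0, 10, by = 2),
                         steps_longitudinal_mm = seq(-10, 10, by = 2),
                         seed = 1L, channels = "both") {
  target_material <- match.arg(target_material)
  structure(list(
    target_material = target_material,
    gd_concentration_mmol_ml = gd_concentration_mmol_ml,
    prescription_Gy = prescription_Gy,
    spacing_mm = spacing_mm, layer_spacing_we_mm = layer_spacing_we_mm,
    extent_cm = extent_cm, voxel_mm = voxel_mm, target_cm = target_cm,
    models = models,
    steps_transverse_mm = steps_transverse_mm,
    steps_longitudinal_mm = steps_longitudinal_mm,
    seed = as.integer(seed), channels = channels
  ), class = "study_config")
}

#' Build the phantom a config describes
#' @param config A `study_config`.
#' @export
config_phantom <- function(config) {
  target <- if (config$target_material == "water") {
    water_material()
  } else {
    dotarem_material(config$gd_concentration_mmol_ml)
  }
  phantom_grid(config$extent_cm, config$voxel_mm, config$target_cm,
               target = target)
}

#' Validate a study configuration
#'
#' Checks units, ranges, grid divisibility and that the scoring sphere
#' encloses the phantom. Never mutates; violations are returned as data.
#'
#' @param config A `study_config`.
#' @return Character vector of violations (empty means ok).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  n <- config$extent_cm * 10 / config$voxel_mm
  if (abs(n - round(n)) > 1e-9) {
    add(sprintf("voxel size %g mm does not divide the %g cm phantom",
                config$voxel_mm, config$extent_cm))
  }
  if (config$target_cm > config$extent_cm) add("target larger than phantom")
  if (config$prescription_Gy <= 0) add("prescription must be positive")
  if (config$spacing_mm <= 0) add("spot spacing must be positive")
  if (config$layer_spacing_we_mm <= 0) add("layer spacing must be positive")
  if (config$gd_concentration_mmol_ml < 0) add("negative Gd concentration")
  half_diag <- config$extent_cm / 2 * sqrt(3)
  if (config$models$sphere_radius_cm < half_diag) {
    add(sprintf("scoring sphere (%.2f cm) smaller than the phantom half-diagonal (%.2f cm)",
                config$models$sphere_radius_cm, half_diag))
  }
  steps <- c(config$steps_transverse_mm, config$steps_longitudinal_mm)
  if (any(abs(steps %% config$voxel_mm) > 1e-9)) {
    add("displacement steps must be multiples of the voxel size")
  }
  if (any(abs(steps) / 10 + config$target_cm / 2 > config$extent_cm / 2)) {
    add("some displacement moves the target outside the phantom")
  }
  v
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(rapply(unclass(config), unclass, how = "replace"), f, ascii = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full study: plan, scenarios, analysis, report files
#'
#' Executes plan optimization, the transverse and longitudinal displacement
#' series and the tracking analysis, writing the spot list, per-scenario
#' tally tables, DVH points and a JSON summary (totals, fits, config hash,
#' seeds, per-stage wall time) under `out_dir`. Idempotent given seed and
#' config.
#'
#' @param config A `study_config`.
#' @param out_dir Output directory (created if needed).
#' @param mode `"expected"` or `"sampled"`.
#' @return Invisibly, a list with the plan, both series and the analysis
#'   tables.
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("study"),
                      mode = "expected") {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config [", config_hash(config), "]:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("gadodose %s",
                         as.character(utils::packageVersion("gadodose"))),
                 sprintf("config_hash %s seed %d", config_hash(config),
                         config$seed))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed [config %s]: %s", name,
                   config_hash(config), conditionMessage(e)), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }
  phantom <- config_phantom(config)
  plan <- stage("plan", plan_treatment(
    phantom, config$prescription_Gy, config$models$model,
    config$models$beam, config$spacing_mm, config$layer_spacing_we_mm))
  write_plan(plan, file.path(out_dir, "plan.csv"))
  tx <- stage("scan_transverse", displacement_series(
    plan, phantom, "x", mode, config$seed, config$models, config$channels,
    steps_mm = config$steps_transverse_mm))
  lz <- stage("scan_longitudinal", displacement_series(
    plan, phantom, "z", mode, config$seed, config$models, config$channels,
    steps_mm = config$steps_longitudinal_mm))
  tallies <- stage("analyze", {
    rows <- lapply(c(tx$results, lz$results), function(r) {
      cbind(axis = r$displacement$axis, mm = r$displacement$mm, r$spots)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(tallies, file.path(out_dir, "tallies.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(series_totals(tx), series_totals(lz)),
                   file.path(out_dir, "totals.csv"), row.names = FALSE)
  track_x <- treatment_tracking(tx)
  track_z <- treatment_tracking(lz)
  summary <- list(
    config_hash = config_hash(config), plan_hash = plan_hash(plan),
    seed = config$seed, mode = mode,
    plan = list(n_spots = nrow(plan$spots), n_layers = nrow(plan$layers),
                energy_min_MeV = min(plan$layers$energy_MeV),
                energy_max_MeV = max(plan$layers$energy_MeV),
                mean_target_dose_Gy = plan$mean_target_dose_Gy,
                d90_Gy = plan$d90_Gy),
    tracking = list(
      transverse_slope = track_x$fits$transverse$slope,
      transverse_r2 = track_x$fits$transverse$r_squared,
      downstream_slope = track_z$fits$downstream$slope,
      upstream_slope = track_z$fits$upstream$slope)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(plan = plan, transverse = tx, longitudinal = lz,
                 tracking = list(transverse = track_x, longitudinal = track_z),
                 out_dir = out_dir))
}
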