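#' Engine configuration bundle
#'
#' Collects the physics model components shared by the planner, scenario
#' engine and emission model.
#'
#' @param model Range-energy model.
#' @param beam Pencil-beam model.
#' @param kshell K-shell x-ray model.
#' @param neutron Neutron production/capture model.
#' @param sphere_radius_cm Scoring sphere inner radius.
#' @param detect_directions Directions per voxel for the detection average.
#' @export
engine_models <- function(model = range_energy_model(),
                          beam = pencil_beam_model(),
                          kshell = kshell_model(),
                          neutron = neutron_model(kshell = kshell),
                          sphere_radius_cm = 8.7,
                          detect_directions = 128) {
  structure(list(model = model, beam = beam, kshell = kshell,
                 neutron = neutron, sphere_radius_cm = sphere_radius_cm,
                 detect_directions = detect_directions),
            class = "engine_models")
}

.valid_steps <- function(mm, voxel_mm) {
  all(abs(mm) <= 10 + 1e-9) && all(abs(mm %% voxel_mm) < 1e-9)
}

#' Run the fixed plan against a displaced phantom
#'
#' The plan is *not* re-optimized: spot positions, energies and weights stay
#' in room coordinates while the target material assignment moves. Dose to
#' target is scored in the displaced target voxels; 43 keV emission is
#' tallied per spot split by channel (PIXE / neutron capture), and detection
#' applies the attenuation-averaged escape survival on the scoring sphere.
#'
#' @param plan A `treatment_plan`.
#' @param phantom The undisplaced `phantom_grid` the plan was made for.
#' @param axis Displacement axis, `"x"` (transverse) or `"z"` (+ = upstream).
#' @param mm Signed displacement (multiple of the voxel size, |mm| <= 10).
#' @param mode `"expected"` (deterministic) or `"sampled"` (Poisson counting
#'   noise, one RNG substream per spot keyed by `(seed, spot_id)`).
#' @param seed Integer seed (sampled mode).
#' @param models An `engine_models` bundle.
#' @param channels Which emission channels to tally (`"both"`, `"pixe"`,
#'   `"capture"`).
#' @param full_grid Also accumulate the cumulative dose grid over the whole
#'   phantom (slower; off by default).
#' @return Object of class `scenario_result`: per-spot records, per-voxel
#'   target dose, DVH, totals, seed and config hashes.
#' @export
run_scenario <- function(plan, phantom, axis = c("x", "z"), mm = 0,
                         mode = c("expected", "sampled"), seed = 1L,
                         models = engine_models(),
                         channels = c("both", "pixe", "capture"),
                         full_grid = FALSE) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  channels <- match.arg(channels)
  if (!.valid_steps(mm, phantom$voxel_cm * 10)) {
    stop("displacement must be a multiple of the voxel size with |mm| <= 10",
         call. = FALSE)
  }
  grid <- displace_target(phantom, axis, mm)
  geo <- precompute_geometry(grid)
  lut <- lut_cache(models$model, models$beam)
  vox <- target_voxel_table(grid, geo)
  spots <- plan$spots
  ns <- nrow(spots)
  nv <- nrow(vox)
  mass_kg <- grid$target$density * grid$voxel_cm^3 * 1e-3
  surv <- survival_map(grid, vox, models$sphere_radius_cm,
                       models$detect_directions)
  dose_vox_total <- numeric(nv)
  rec <- data.frame(spot_id = spots$spot_id, layer = spots$layer,
                    energy_MeV = spots$energy_MeV, x_mm = spots$x_mm,
                    y_mm = spots$y_mm, weight = spots$weight_protons,
                    dose_target_Gy = 0, emitted_pixe = 0,
                    emitted_capture = 0, detected_pixe = 0,
                    detected_capture = 0, detected_total = 0,
                    detected_sampled = NA_real_)
  cum <- if (full_grid) array(0, dim = rep(grid$n, 3)) else NULL
  idx <- cbind(vox$ix, vox$iy, vox$iz)
  dwe <- geo$dwe[idx]
  do_pixe <- channels %in% c("both", "pixe")
  do_capt <- channels %in% c("both", "capture")
  for (s in seq_len(ns)) {
    sp <- spots[s, ]
    w <- sp$weight_protons
    if (mode == "sampled") {
      w <- with_seed(substream_seed(seed, sp$spot_id, 1), rpois_big(1, w))
    }
    g <- lateral_mass(grid, vox, sp$x_mm, sp$y_mm, models$beam)
    dd <- lut(sp$energy_MeV)(vox$we_mid)
    dose_vec <- w * dd * dwe * g * .MEV_TO_J / mass_kg
    dose_vox_total <- dose_vox_total + dose_vec
    rec$dose_target_Gy[s] <- mean(dose_vec)
    pix_v <- if (do_pixe && grid$target$gd_number_density > 0) {
      pixe_per_voxel(w, sp$energy_MeV, g, vox, grid, models$kshell,
                     models$model, models$beam)
    } else numeric(nv)
    cap_v <- if (do_capt) {
      sp_w <- sp; sp_w$weight_protons <- w
      capture_per_voxel(grid, sp_w, vox, models$neutron, models$model,
                        models$beam) * models$neutron$photons_per_capture
    } else numeric(nv)
    rec$emitted_pixe[s] <- sum(pix_v)
    rec$emitted_capture[s] <- sum(cap_v)
    rec$detected_pixe[s] <- sum(pix_v * surv)
    rec$detected_capture[s] <- sum(cap_v * surv)
    rec$detected_total[s] <- rec$detected_pixe[s] + rec$detected_capture[s]
    if (mode == "sampled") {
      rec$detected_sampled[s] <- with_seed(
        substream_seed(seed, sp$spot_id, 2),
        rpois_big(1, rec$detected_total[s]))
    }
    if (full_grid) {
      cum <- cum + spot_dose(grid, sp$energy_MeV, sp$x_mm, sp$y_mm, w,
                             models$model, models$beam, geo = geo,
                             lut = lut)$dose
    }
  }
  dvh_obj <- dvh(dose_vox_total, plan$prescription_Gy)
  structure(list(
    displacement = list(axis = axis, mm = mm),
    spots = rec,
    target_dose_vox = dose_vox_total,
    dvh = dvh_obj,
    totals = list(
      dose_target_Gy = sum(rec$dose_target_Gy),
      emitted_pixe = sum(rec$emitted_pixe),
      emitted_capture = sum(rec$emitted_capture),
      detected_pixe = sum(rec$detected_pixe),
      detected_capture = sum(rec$detected_capture),
      detected_total = sum(rec$detected_total),
      detected_sampled = if (mode == "sampled") sum(rec$detected_sampled)
                         else NA_real_
    ),
    mode = mode, seed = seed, channels = channels,
    cumulative_dose = if (full_grid) new_dose_grid(cum, grid) else NULL,
    plan_hash = plan_hash(plan),
    config_hash = models_hash(models)
  ), class = "scenario_result")
}

# Poisson sampler that stays valid for large means (normal approximation
# above the safe rpois range).
rpois_big <- function(n, lambda) {
  if (lambda < 1e9) as.numeric(stats::rpois(n, lambda))
  else round(stats::rnorm(n, lambda, sqrt(lambda)))
}

models_hash <- function(models) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(rapply(unclass(models), unclass, how = "replace"), f, ascii = TRUE)
  unname(tools::md5sum(f))
}

#' Canonical displacement series
#'
#' Transverse (+x): steps 0, 2, ..., 10 mm. Longitudinal (z): steps -10 ...
#' +10 mm in 2 mm increments (+ = upstream). All scenarios share the fixed
#' plan and configuration.
#'
#' @inheritParams run_scenario
#' @param steps_mm Optional explicit step set (overrides the canonical one).
#' @return Object of class `scenario_series` (list of `scenario_result`).
#' @export
displacement_series <- function(plan, phantom, axis = c("x", "z"),
                                mode = c("expected", "sampled"), seed = 1L,
                                models = engine_models(),
                                channels = "both", steps_mm = NULL,
                                full_grid = FALSE) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (is.null(steps_mm)) {
    steps_mm <- if (axis == "x") seq(0, 10, by = 2) else seq(-10, 10, by = 2)
  }
  results <- lapply(steps_mm, function(mm)
    run_scenario(plan, phantom, axis, mm, mode, seed, models, channels,
                 full_grid))
  structure(list(axis = axis, steps_mm = steps_mm, results = results,
                 mode = mode, seed = seed,
                 plan_hash = plan_hash(plan),
                 config_hash = models_hash(models)),
            class = "scenario_series")
}

#' Totals table of a displacement series
#'
#' @param series A `scenario_series`.
#' @return data.frame with one row per scenario: displacement, integral
#'   target dose and detected 43 keV totals per channel.
#' @export
series_totals <- function(series) {
  do.call(rbind, lapply(series$results, function(r) {
    data.frame(axis = r$displacement$axis, mm = r$displacement$mm,
               dose_target_Gy = r$totals$dose_target_Gy,
               detected_pixe = r$totals$detected_pixe,
               detected_capture = r$totals$detected_capture,
               detected_total = r$totals$detected_total,
               v95 = v_at(r$dvh, 0.95))
  }))
}

#' Batch estimate of counting-statistics uncertainty on series totals
#'
#' Runs `n_batches` independent sampled replicates of one scenario and
#' reports mean and standard deviation of the totals (a batch substitute for
#' history-by-history estimators; the surrogate engine is analytic, so noise
#' enters only through the sampled fluence and counts).
#'
#' @inheritParams run_scenario
#' @param n_batches Number of replicates.
#' @return List with `mean`, `sd` of total dose and detected signal.
#' @export
batch_uncertainty <- function(plan, phantom, axis = "x", mm = 0,
                              n_batches = 10, seed = 1L,
                              models = engine_models()) {
  tot <- vapply(seq_len(n_batches), function(b) {
    r <- run_scenario(plan, phantom, axis, mm, mode = "sampled",
                      seed = substream_seed(seed, b), models = models)
    c(dose = r$totals$dose_target_Gy, signal = r$totals$detected_sampled)
  }, numeric(2))
  list(mean = rowMeans(tot), sd = apply(tot, 1, stats::sd))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s%+g mm (%s mode)\n",
              x$displacement$axis, x$displacement$mm, x$mode))
  cat(sprintf("  target dose %.3f Gy | detected 43 keV %.4g (PIXE %.4g, capture %.4g)\n",
              x$totals$dose_target_Gy, x$totals$detected_total,
              x$totals$detected_pixe, x$totals$detected_capture))
  cat(sprintf("  V95 %.1f%%  D90 %.3f Gy\n", 100 * v_at(x$dvh, 0.95),
              d_at(x$dvh, 0.90)))
  invisible(x)
}

#' @export
print.scenario_series <- function(x, ...) {
  cat(sprintf("<scenario_series> axis %s, %d scenarios (%s mode)\n",
              x$axis, length(x$results), x$mode))
  print(series_totals(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.scenario_series <- function(x, ...) {
  tot <- series_totals(x)
  graphics::plot(tot$dose_target_Gy, tot$detected_total,
                 xlab = "integral target dose (Gy)",
                 ylab = "detected 43 keV counts",
                 pch = ifelse(tot$mm >= 0, 19, 1), ...)
  graphics::text(tot$dose_target_Gy, tot$detected_total,
                 labels = sprintf("%+g", tot$mm), pos = 3, cex = 0.7)
  invisible(x)
}
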