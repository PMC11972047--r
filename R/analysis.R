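#' Cumulative dose-volume histogram over the target
#'
#' Empirical cumulative DVH over target voxel doses: `V(d)` is the fraction
#' of the target receiving at least `d` Gy (1 at dose 0, monotone
#' non-increasing).
#'
#' @param dose Numeric vector of per-voxel target doses (Gy), or a
#'   `dose_grid` together with a logical `target` mask.
#' @param prescription_Gy Prescription used by the V95 accessor.
#' @param target Optional logical mask when `dose` is a `dose_grid`.
#' @return Object of class `dvh_curve`.
#' @export
dvh <- function(dose, prescription_Gy = 4, target = NULL) {
  if (inherits(dose, "dose_grid")) {
    stopifnot(!is.null(target))
    dose <- dose$dose[target]
  }
  if (length(dose) == 0) stop("empty target", call. = FALSE)
  stopifnot(all(dose >= 0))
  sorted <- sort(dose, decreasing = TRUE)
  structure(list(dose_sorted = sorted, n = length(sorted),
                 prescription_Gy = prescription_Gy),
            class = "dvh_curve")
}

#' Volume fraction at a dose level
#'
#' `v_at(x, f)` returns the fraction of the target receiving at least
#' `f x prescription`; `v_at_dose` takes an absolute dose in Gy. V95 is
#' `v_at(x, 0.95)`.
#'
#' @param x A `dvh_curve`.
#' @param fraction_of_prescription Dose level as a fraction of prescription.
#' @export
v_at <- function(x, fraction_of_prescription) {
  v_at_dose(x, fraction_of_prescription * x$prescription_Gy)
}

#' @rdname v_at
#' @param dose_Gy Absolute dose level.
#' @export
v_at_dose <- function(x, dose_Gy) {
  mean(x$dose_sorted >= dose_Gy)
}

#' Dose received by at least a volume fraction (DVH quantile)
#'
#' `d_at(x, 0.90)` is D90: the highest dose received by at least 90% of the
#' target volume.
#'
#' @param x A `dvh_curve`.
#' @param volume_fraction Volume fraction in (0, 1].
#' @export
d_at <- function(x, volume_fraction) {
  stopifnot(volume_fraction > 0, volume_fraction <= 1)
  x$dose_sorted[ceiling(volume_fraction * x$n)]
}

# D-at-fraction on a raw dose vector (used by the planner).
d_at_fraction <- function(dose, volume_fraction) {
  sort(dose, decreasing = TRUE)[ceiling(volume_fraction * length(dose))]
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, prescription %.3g Gy\n",
              x$n, x$prescription_Gy))
  cat(sprintf("  V95 %.1f%% | V100 %.1f%% | D90 %.3f Gy | mean %.3f Gy\n",
              100 * v_at(x, 0.95), 100 * v_at(x, 1),
              d_at(x, 0.90), mean(x$dose_sorted)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  d <- sort(unique(c(0, x$dose_sorted)))
  v <- vapply(d, function(dd) v_at_dose(x, dd), numeric(1))
  graphics::plot(d, 100 * v, type = "s", xlab = "dose (Gy)",
                 ylab = "volume (%)", ylim = c(0, 100), ...)
  graphics::abline(v = 0.95 * x$prescription_Gy, lty = 3, col = "grey60")
  invisible(x)
}

#' Ordinary least-squares dose-signal correlation
#'
#' Fits `signal = intercept + slope x dose` over per-spot records and reports
#' the slope with its standard error and R-squared.
#'
#' @param dose Per-spot doses (Gy).
#' @param signal Per-spot detected 43 keV counts.
#' @param group Optional group label carried into the output.
#' @param weights Optional OLS weights (e.g. `1/sigma^2` Poisson weights for
#'   sampled-mode fits; default unweighted).
#' @return Object of class `dose_signal_fit`.
#' @export
per_spot_correlation <- function(dose, signal, group = NA_character_,
                                 weights = NULL) {
  if (length(dose) < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(dose) == 0) {
    stop(sprintf("degenerate abscissa (all doses equal) in group '%s'",
                 group), call. = FALSE)
  }
  fit <- stats::lm(signal ~ dose, weights = weights)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients["dose", "Std. Error"],
                 r_squared = sm$r.squared,
                 n = length(dose), group = group, lm = fit),
            class = "dose_signal_fit")
}

#' @export
print.dose_signal_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_signal_fit>%s slope %.4g +- %.3g counts/Gy, intercept %.4g, R^2 %.4f (n=%d)\n",
    if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
    x$slope, x$slope_se, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Partition plan spots into analysis groups
#'
#' `"corners"`: the four corner stacks of the lateral lattice (one group per
#' corner position, across all energy layers). `"energy_layers"`: one group
#' per layer. `"position"`: one group per lateral `(x, y)` position.
#'
#' @param plan A `treatment_plan` (or bare spots data.frame).
#' @param mode Grouping mode.
#' @return Named list of integer vectors of `spot_id`s.
#' @export
group_spots <- function(plan, mode = c("corners", "energy_layers",
                                       "position")) {
  mode <- match.arg(mode)
  spots <- if (inherits(plan, "treatment_plan")) plan$spots else plan
  key <- switch(mode,
    corners = {
      xm <- max(abs(spots$x_mm)); ym <- max(abs(spots$y_mm))
      corner <- abs(spots$x_mm) == xm & abs(spots$y_mm) == ym
      k <- ifelse(corner, sprintf("(%g,%g)", spots$x_mm, spots$y_mm), NA)
      k
    },
    energy_layers = sprintf("layer_%02d", spots$layer),
    position = sprintf("(%g,%g)", spots$x_mm, spots$y_mm)
  )
  keep <- !is.na(key)
  split(spots$spot_id[keep], key[keep])
}

#' Per-group percent change between two scenarios
#'
#' `100 x (displaced - baseline) / baseline` of group-summed dose-to-target
#' and detected 43 keV signal. Groups with zero baseline are flagged
#' (`NA` with `baseline_zero = TRUE`), never divided.
#'
#' @param baseline,displaced `scenario_result`s sharing the same plan hash.
#' @param grouping Named list of spot-id groups (see [group_spots()]).
#' @return data.frame, one row per group: `group`, `dose_pct`, `signal_pct`,
#'   baseline/displaced sums and `baseline_zero`.
#' @export
percent_change <- function(baseline, displaced, grouping) {
  if (!identical(baseline$plan_hash, displaced$plan_hash)) {
    stop("scenario results come from different plans (hash mismatch)",
         call. = FALSE)
  }
  rows <- lapply(names(grouping), function(gname) {
    ids <- grouping[[gname]]
    b <- baseline$spots[baseline$spots$spot_id %in% ids, ]
    d <- displaced$spots[displaced$spots$spot_id %in% ids, ]
    b_dose <- sum(b$dose_target_Gy); d_dose <- sum(d$dose_target_Gy)
    b_sig <- sum(b$detected_total); d_sig <- sum(d$detected_total)
    zero <- b_dose == 0 || b_sig == 0
    data.frame(group = gname,
               dose_pct = if (b_dose > 0) 100 * (d_dose - b_dose) / b_dose
                          else NA_real_,
               signal_pct = if (b_sig > 0) 100 * (d_sig - b_sig) / b_sig
                            else NA_real_,
               dose_baseline = b_dose, dose_displaced = d_dose,
               signal_baseline = b_sig, signal_displaced = d_sig,
               baseline_zero = zero)
  })
  do.call(rbind, rows)
}

#' Dose-signal slope versus proton energy at the target
#'
#' For each longitudinal scenario: the mean entry kinetic energy of the
#' highest-energy layer's protons at the displaced target's proximal face,
#' and the per-spot dose-signal OLS slope of that scenario. Sorted by energy.
#'
#' @param series A longitudinal `scenario_series`.
#' @param phantom The undisplaced phantom (for ray tracing).
#' @param models Engine models.
#' @return data.frame: `mm`, `entry_KE_MeV`, `slope`, `slope_se`,
#'   `r_squared`.
#' @export
slope_vs_energy <- function(series, phantom, models = engine_models()) {
  rows <- lapply(series$results, function(r) {
    mm <- r$displacement$mm
    grid <- displace_target(phantom, series$axis, mm)
    off <- grid$target_offset_mm / 10
    z_prox <- off[3] + grid$t_half
    last <- r$spots[r$spots$energy_MeV == max(r$spots$energy_MeV), ]
    ke <- vapply(seq_len(nrow(last)), function(i) {
      we <- wepl_at_plane(grid, last$x_mm[i], last$y_mm[i], z_prox)
      energy_at_depth(last$energy_MeV[i], we, models$model)
    }, numeric(1))
    fit <- per_spot_correlation(r$spots$dose_target_Gy,
                                r$spots$detected_total,
                                group = sprintf("%s%+d mm", series$axis, mm))
    data.frame(mm = mm, entry_KE_MeV = mean(ke), slope = fit$slope,
               slope_se = fit$slope_se, r_squared = fit$r_squared)
  })
  out <- do.call(rbind, rows)
  out[order(out$entry_KE_MeV), ]
}

#' Cumulative treatment tracking over a displacement series
#'
#' Per-scenario integral target dose and total detected 43 keV signal, with a
#' single dose-signal OLS fit for a transverse series and separate
#' upstream/downstream branch fits (both including the baseline) for a
#' longitudinal series. Slope signs are reported: the downstream branch is
#' expected positive (signal falls with dose), the upstream branch negative
#' (signal rises as dose falls).
#'
#' @param series A `scenario_series`.
#' @return List with `totals` (data.frame) and `fits` (named list of
#'   `dose_signal_fit`).
#' @export
treatment_tracking <- function(series) {
  tot <- series_totals(series)
  fits <- if (series$axis == "x") {
    list(transverse = per_spot_correlation(tot$dose_target_Gy,
                                           tot$detected_total,
                                           group = "transverse"))
  } else {
    down <- tot[tot$mm <= 0, ]
    up <- tot[tot$mm >= 0, ]
    list(
      downstream = per_spot_correlation(down$dose_target_Gy,
                                        down$detected_total,
                                        group = "downstream"),
      upstream = per_spot_correlation(up$dose_target_Gy,
                                      up$detected_total,
                                      group = "upstream")
    )
  }
  list(totals = tot, fits = fits,
       slope_signs = vapply(fits, function(f) sign(f$slope), numeric(1)))
}
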