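#' Select energy layers for a scanning plan
#'
#' Bragg-peak water-equivalent depths run from the distal target edge upstream
#' in steps of `layer_spacing_we_mm` until the proximal edge is reached or
#' passed; the deepest layer sits exactly at the distal edge's WE depth.
#' Energies come from inverting the range-energy model.
#'
#' @param grid A `phantom_grid` (undisplaced planning geometry).
#' @param model A `range_energy_model`.
#' @param layer_spacing_we_mm Layer spacing in WE mm (default 2, equal to the
#'   voxel size).
#' @return data.frame with columns `layer`, `energy_MeV`, `peak_we_cm`,
#'   sorted descending in energy (layer 1 = distal).
#' @export
select_energy_layers <- function(grid, model = range_energy_model(),
                                 layer_spacing_we_mm = 2) {
  stopifnot(layer_spacing_we_mm > 0)
  off <- grid$target_offset_mm / 10
  z_prox <- off[3] + grid$t_half
  z_dist <- off[3] - grid$t_half
  prox <- wepl_at_plane(grid, off[1] * 10, off[2] * 10, z_prox)
  dist <- wepl_at_plane(grid, off[1] * 10, off[2] * 10, z_dist)
  if (!is.null(model$table) && dist > max(model$table$range_cm)) {
    stop("target deeper than the range-energy table maximum", call. = FALSE)
  }
  step <- layer_spacing_we_mm / 10
  k <- 0:max(0, floor((dist - prox) / step + 1e-9))
  depths <- dist - k * step
  data.frame(layer = seq_along(depths),
             energy_MeV = energy_from_range(depths, model),
             peak_we_cm = depths)
}

#' Lateral spot lattice over the target cross-section
#'
#' Symmetric grid with the given spacing covering the target cross-section;
#' for a 2 x 2 cm^2 target and 3 mm spacing this yields the 49 positions
#' with x, y in \{-9, -6, ..., 9\} mm (corners at (+-9, +-9) mm).
#'
#' @param target_cross_cm Target cross-section side (cm).
#' @param spacing_mm Lateral spot spacing (mm).
#' @return data.frame with columns `x_mm`, `y_mm`.
#' @export
place_spots <- function(target_cross_cm = 2, spacing_mm = 3) {
  stopifnot(spacing_mm > 0)
  half_mm <- target_cross_cm * 10 / 2
  k <- floor((half_mm - 1e-9) / spacing_mm)
  pos <- spacing_mm * (-k:k)
  expand.grid(x_mm = pos, y_mm = pos, KEEP.OUT.ATTRS = FALSE)
}

#' Plan skeleton: layers x lateral lattice, unit weights
#'
#' @inheritParams select_energy_layers
#' @param spacing_mm Lateral spot spacing (mm).
#' @return data.frame of spots: `spot_id`, `layer`, `energy_MeV`, `x_mm`,
#'   `y_mm`, `weight_protons` (all 1).
#' @export
plan_skeleton <- function(grid, model = range_energy_model(),
                          spacing_mm = 3, layer_spacing_we_mm = 2) {
  layers <- select_energy_layers(grid, model, layer_spacing_we_mm)
  lat <- place_spots(grid$target_extent, spacing_mm)
  spots <- do.call(rbind, lapply(seq_len(nrow(layers)), function(i) {
    data.frame(layer = layers$layer[i], energy_MeV = layers$energy_MeV[i],
               x_mm = lat$x_mm, y_mm = lat$y_mm, weight_protons = 1)
  }))
  spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
  attr(spots, "layers") <- layers
  spots
}

# Average weights over the lateral reflection group {x -> +-x, y -> +-y}.
# The influence operator commutes with these reflections (symmetric phantom,
# symmetric lattice), so any reflection of an NNLS minimizer is a minimizer
# and so is their average (the objective is convex): this picks the symmetric
# solution from the optimal set instead of an arbitrary sparse vertex.
symmetrize_weights <- function(spots, weights) {
  key <- function(x, y) paste(spots$layer, x, y)
  here <- key(spots$x_mm, spots$y_mm)
  out <- weights
  for (sgn in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    m <- match(key(sgn[1] * spots$x_mm, sgn[2] * spots$y_mm), here)
    if (anyNA(m)) return(weights) # lattice not symmetric: leave as is
    out <- out + weights[m]
  }
  out / 4
}

# Nonnegative least squares: accelerated projected gradient (FISTA with
# adaptive restart) on the normal equations, followed by cyclic coordinate
# descent polish. Handles the strongly correlated influence columns of
# closely spaced Gaussian spots.
nnls_pg <- function(A, b, maxit = 4000, tol = 1e-10, polish_sweeps = 50) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  Lip <- max(rowSums(abs(AtA))) # cheap upper bound on the spectral norm
  w <- y <- pmax(0, Atb / diag(AtA))
  t_k <- 1
  f_old <- Inf
  for (it in seq_len(maxit)) {
    g <- AtA %*% y - Atb
    w_new <- pmax(0, y - g / Lip)
    f <- sum((AtA %*% w_new) * w_new) / 2 - sum(Atb * w_new)
    if (f > f_old) { # restart acceleration
      y <- w
      t_k <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    if (max(abs(w_new - w)) <= tol * max(1, max(w_new))) {
      w <- w_new
      break
    }
    w <- w_new
    t_k <- t_new
    f_old <- f
  }
  # coordinate-descent polish: exact per-coordinate minimization
  d <- diag(AtA)
  g <- as.vector(AtA %*% w - Atb)
  for (sw in seq_len(polish_sweeps)) {
    delta_max <- 0
    for (j in seq_along(w)) {
      wj <- max(0, w[j] - g[j] / d[j])
      dj <- wj - w[j]
      if (dj != 0) {
        g <- g + AtA[, j] * dj
        w[j] <- wj
        delta_max <- max(delta_max, abs(dj))
      }
    }
    if (delta_max <= tol * max(1, max(w))) break
  }
  as.vector(w)
}

#' Optimize spot weights to a uniform target prescription
#'
#' Nonnegative least squares over the (undisplaced) target voxels only, with
#' the deterministic dose engine: minimizes `sum((dose - prescription)^2)`
#' subject to `weight >= 0`. No margins, no organ-at-risk terms.
#'
#' @param grid Planning `phantom_grid` (target undisplaced).
#' @param prescription_Gy Uniform target dose (Gy), default 4.
#' @param model,beam Engine models.
#' @param spacing_mm,layer_spacing_we_mm Lattice parameters.
#' @return Object of class `treatment_plan`.
#' @export
plan_treatment <- function(grid, prescription_Gy = 4,
                           model = range_energy_model(),
                           beam = pencil_beam_model(),
                           spacing_mm = 3, layer_spacing_we_mm = 2) {
  skeleton <- plan_skeleton(grid, model, spacing_mm, layer_spacing_we_mm)
  geo <- precompute_geometry(grid)
  vox <- which(geo$mask, arr.ind = TRUE)
  vox <- data.frame(ix = vox[, 1], iy = vox[, 2], iz = vox[, 3])
  A <- spot_influence(grid, skeleton, vox, model, beam, geo = geo)
  if (max(A) <= 0) stop("infeasible plan: zero influence on target",
                        call. = FALSE)
  # scale columns to O(1) weights for conditioning; rescale after the solve
  scale_w <- prescription_Gy / pmax(colSums(A), 1e-300)
  w <- nnls_pg(sweep(A, 2, scale_w, "*"), rep(prescription_Gy, nrow(vox)))
  weights <- symmetrize_weights(skeleton, w * scale_w)
  dose_vox <- as.vector(A %*% weights)
  skeleton$weight_protons <- weights
  structure(list(
    spots = skeleton,
    layers = attr(skeleton, "layers"),
    prescription_Gy = prescription_Gy,
    target_material = grid$target$name,
    spacing_mm = spacing_mm,
    layer_spacing_we_mm = layer_spacing_we_mm,
    total_protons = sum(weights),
    mean_target_dose_Gy = mean(dose_vox),
    d90_Gy = d_at_fraction(dose_vox, 0.90)
  ), class = "treatment_plan")
}

#' Rescale plan fluence to a fixed total proton count
#'
#' Relative weights are preserved; the dose engine is linear, so every dose
#' and emission quantity scales by the same factor.
#'
#' @param plan A `treatment_plan`.
#' @param total_protons Desired total (e.g. 1e9).
#' @export
downscale_fluence <- function(plan, total_protons) {
  stopifnot(total_protons > 0)
  f <- total_protons / sum(plan$spots$weight_protons)
  plan$spots$weight_protons <- plan$spots$weight_protons * f
  plan$total_protons <- total_protons
  plan$mean_target_dose_Gy <- plan$mean_target_dose_Gy * f
  plan$d90_Gy <- plan$d90_Gy * f
  plan
}

#' Write / read a spot list as CSV
#'
#' Header `layer,energy_MeV,x_mm,y_mm,weight_protons`, one row per spot;
#' floats are written with 17 significant digits so the round trip is
#' lossless.
#'
#' @param plan A `treatment_plan` (or a bare spots data.frame).
#' @param path CSV path.
#' @export
write_plan <- function(plan, path) {
  spots <- if (inherits(plan, "treatment_plan")) plan$spots else plan
  out <- spots[, c("layer", "energy_MeV", "x_mm", "y_mm", "weight_protons")]
  for (cn in c("energy_MeV", "x_mm", "y_mm", "weight_protons")) {
    out[[cn]] <- formatC(out[[cn]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  spots <- utils::read.csv(path, colClasses = c(
    layer = "integer", energy_MeV = "numeric", x_mm = "numeric",
    y_mm = "numeric", weight_protons = "numeric"))
  cbind(spot_id = seq_len(nrow(spots)), spots)
}

# md5 of the spot list (fixed-plan contract across scenarios). The hash is
# taken over a canonical 17-significant-digit text rendering so it is
# invariant to vector internals (e.g. a CSV round trip).
plan_hash <- function(plan) {
  spots <- if (inherits(plan, "treatment_plan")) plan$spots else plan
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g", as.integer(spots$layer),
                     spots$energy_MeV, spots$x_mm, spots$y_mm,
                     spots$weight_protons), f)
  unname(tools::md5sum(f))
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("<treatment_plan> %d spots / %d energy layers (%s target)\n",
              nrow(x$spots), nrow(x$layers), x$target_material))
  cat(sprintf("  energies: %.2f - %.2f MeV;  lattice %g mm;  layers %g mm WE\n",
              min(x$layers$energy_MeV), max(x$layers$energy_MeV),
              x$spacing_mm, x$layer_spacing_we_mm))
  cat(sprintf("  prescription %.3g Gy;  mean target dose %.3f Gy;  D90 %.3f Gy\n",
              x$prescription_Gy, x$mean_target_dose_Gy, x$d90_Gy))
  cat(sprintf("  total protons %.4g\n", x$total_protons))
  invisible(x)
}

#' @export
summary.treatment_plan <- function(object, ...) {
  spots <- object$spots
  per_layer <- stats::aggregate(weight_protons ~ layer + energy_MeV,
                                data = spots, FUN = sum)
  per_layer <- per_layer[order(-per_layer$energy_MeV), ]
  per_layer$weight_share <- per_layer$weight_protons /
    sum(per_layer$weight_protons)
  out <- list(plan = object, per_layer = per_layer)
  class(out) <- "summary.treatment_plan"
  out
}

#' @export
print.summary.treatment_plan <- function(x, ...) {
  print(x$plan)
  cat("  per-layer proton share:\n")
  print(data.frame(layer = x$per_layer$layer,
                   energy_MeV = round(x$per_layer$energy_MeV, 2),
                   share = round(x$per_layer$weight_share, 3)),
        row.names = FALSE)
  invisible(x)
}
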