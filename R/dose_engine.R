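#' Bragg-Kleeman range-energy model
#'
#' `R = alpha * E^p` (cm water-equivalent, E in MeV). The default constants
#' (`alpha = 0.0022`, `p = 1.77`) are calibrated against the embedded CSDA
#' range table for water in the 50-100 MeV window; a tabulated override
#' (data.frame with columns `energy_MeV`, `range_cm`) wins when supplied.
#'
#' @param alpha Range constant (cm MeV^-p).
#' @param p Range exponent (must lie in (1, 2)).
#' @param table Optional tabulated range-energy override.
#' @return Object of class `range_energy_model`.
#' @export
range_energy_model <- function(alpha = 0.0022, p = 1.77, table = NULL) {
  stopifnot(alpha > 0, p > 1, p < 2)
  if (!is.null(table)) {
    stopifnot(all(c("energy_MeV", "range_cm") %in% names(table)),
              !is.unsorted(table$energy_MeV, strictly = TRUE),
              !is.unsorted(table$range_cm, strictly = TRUE))
  }
  structure(list(alpha = alpha, p = p, table = table),
            class = "range_energy_model")
}

# CSDA ranges of protons in water (g/cm^2 ~ cm), NIST PSTAR excerpt used as
# an independent calibration check for the power-law constants.
.CSDA_WATER <- data.frame(
  energy_MeV = c(50,    60,    70,    80,    90,    100),
  range_cm   = c(2.227, 3.093, 4.080, 5.184, 6.398, 7.718)
)

#' Proton range in water-equivalent cm
#' @param E_MeV Kinetic energy (MeV), vectorized.
#' @param model A `range_energy_model`.
#' @export
range_from_energy <- function(E_MeV, model = range_energy_model()) {
  stopifnot(all(E_MeV >= 0))
  if (!is.null(model$table)) {
    ex <- exp(stats::approx(log(model$table$energy_MeV),
                            log(model$table$range_cm),
                            xout = log(pmax(E_MeV, 1e-12)), rule = 2)$y)
    return(ifelse(E_MeV == 0, 0, ex))
  }
  model$alpha * E_MeV^model$p
}

#' Inverse of [range_from_energy()]
#' @param R_cm Water-equivalent range (cm), vectorized.
#' @inheritParams range_from_energy
#' @export
energy_from_range <- function(R_cm, model = range_energy_model()) {
  stopifnot(all(R_cm >= 0))
  if (!is.null(model$table)) {
    ex <- exp(stats::approx(log(model$table$range_cm),
                            log(model$table$energy_MeV),
                            xout = log(pmax(R_cm, 1e-12)), rule = 2)$y)
    return(ifelse(R_cm == 0, 0, ex))
  }
  (R_cm / model$alpha)^(1 / model$p)
}

#' Pencil-beam lateral / straggling model
#'
#' @param sigma0_mm Lateral spot sigma at the phantom entrance (mm).
#' @param straggling_fraction Gaussian range-straggling width as a fraction
#'   of the range (`sigma_R = fraction x R`).
#' @param mcs_growth_mm_per_cm Linear lateral sigma growth with physical
#'   depth (mm of sigma per cm of depth), a multiple-Coulomb-scattering
#'   stand-in.
#' @param nuclear_loss_per_cm Fluence-loss rate per WE cm (protons removed by
#'   nonelastic nuclear interactions; their energy is treated as not locally
#'   deposited).
#' @return Object of class `pencil_beam_model`.
#' @export
pencil_beam_model <- function(sigma0_mm = 4, straggling_fraction = 0.012,
                              mcs_growth_mm_per_cm = 0.45,
                              nuclear_loss_per_cm = 0.005) {
  stopifnot(sigma0_mm >= 0, straggling_fraction >= 0,
            mcs_growth_mm_per_cm >= 0, nuclear_loss_per_cm >= 0)
  structure(list(sigma0_mm = sigma0_mm,
                 straggling_fraction = straggling_fraction,
                 mcs_growth_mm_per_cm = mcs_growth_mm_per_cm,
                 nuclear_loss_per_cm = nuclear_loss_per_cm),
            class = "pencil_beam_model")
}

lateral_sigma_cm <- function(beam, depth_cm) {
  (beam$sigma0_mm + beam$mcs_growth_mm_per_cm * depth_cm) / 10
}

# Surviving primary fluence fraction at WE depth d for a beam of range R.
fluence_factor <- function(beam, d_cm, R_cm) {
  pmax(0, 1 - beam$nuclear_loss_per_cm * pmin(d_cm, R_cm))
}

#' Analytic Bragg curve: depth dose per proton (MeV per WE cm)
#'
#' Power-law stopping `S(u) = dE/du` of the Bragg-Kleeman model for residual
#' range `u`, convolved with Gaussian range straggling of width
#' `straggling_fraction x R`, times the surviving primary fluence. The
#' substitution `v = u^(1/p)` removes the integrable end-of-range
#' singularity, so a fixed Gauss-Legendre rule converges rapidly.
#'
#' @param E_MeV Beam energy (single value).
#' @param depth_cm Water-equivalent depth(s), vectorized.
#' @param model A `range_energy_model` (power-law branch is used).
#' @param beam A `pencil_beam_model`.
#' @param nodes Number of quadrature nodes.
#' @return Dose rate in MeV/cm per proton at each depth.
#' @export
depth_dose <- function(E_MeV, depth_cm, model = range_energy_model(),
                       beam = pencil_beam_model(), nodes = 64) {
  stopifnot(length(E_MeV) == 1, E_MeV > 0, all(depth_cm >= 0))
  R <- model$alpha * E_MeV^model$p
  q <- 1 / model$p
  sig <- max(beam$straggling_fraction * R, 1e-6)
  m <- R - depth_cm
  out <- numeric(length(depth_cm))
  live <- m > -5 * sig
  if (any(live)) {
    vmax <- (pmax(m[live], 0) + 6 * sig)^q
    gl <- pracma::gaussLegendre(nodes, 0, 1)
    # nodes scaled per depth: v = t * vmax
    tv <- outer(vmax, gl$x)                     # [nd x nodes]
    phi <- stats::dnorm(tv^(1 / q) - m[live], sd = sig)
    out[live] <- (phi %*% gl$w) * vmax / model$alpha^q
  }
  out * fluence_factor(beam, depth_cm, R)
}

# Dense lookup of depth_dose for one energy; returns an approxfun.
depth_dose_lut <- function(E_MeV, model, beam, step_cm = 0.01) {
  R <- model$alpha * E_MeV^model$p
  sig <- max(beam$straggling_fraction * R, 1e-6)
  d <- seq(0, R + 6 * sig, by = step_cm)
  stats::approxfun(d, depth_dose(E_MeV, d, model, beam), yleft = NA,
                   yright = 0)
}

# Cache of depth-dose LUTs keyed by energy (per models pair).
lut_cache <- function(model, beam) {
  env <- new.env(parent = emptyenv())
  function(E) {
    key <- sprintf("%.6f", E)
    f <- env[[key]]
    if (is.null(f)) {
      f <- depth_dose_lut(E, model, beam)
      env[[key]] <- f
    }
    f
  }
}

# Gaussian mass fraction of a lateral profile integrated over [lo, hi] (cm).
gauss_band <- function(lo, hi, mu, sigma) {
  stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
}

#' Dose grid of a single spot over the full phantom
#'
#' Deposits `weight x depth_dose(E, WE depth) x voxel WE thickness` laterally
#' weighted by the exact Gaussian integral over each voxel cross-section,
#' converted to Gy with the local voxel mass. Linear in `weight`.
#'
#' @param grid A `phantom_grid`.
#' @param energy_MeV Spot energy.
#' @param x_mm,y_mm Spot lateral position (mm).
#' @param weight Number of protons (>= 0).
#' @param model,beam Engine models.
#' @param geo Optional cached [precompute_geometry()] result.
#' @param lut Optional cached LUT factory from `lut_cache`.
#' @return Object of class `dose_grid`: 3-d array of dose (Gy) plus metadata.
#' @export
spot_dose <- function(grid, energy_MeV, x_mm, y_mm, weight,
                      model = range_energy_model(),
                      beam = pencil_beam_model(),
                      geo = NULL, lut = NULL) {
  stopifnot(weight >= 0)
  if (is.null(geo)) geo <- precompute_geometry(grid)
  if (is.null(lut)) lut <- lut_cache(model, beam)
  n <- grid$n
  dose <- array(0, dim = c(n, n, n))
  x0 <- x_mm / 10; y0 <- y_mm / 10
  if (abs(x0) >= grid$half || abs(y0) >= grid$half) {
    warning("spot axis outside the phantom; returning zero grid")
    return(new_dose_grid(dose, grid, provenance = "off-phantom spot"))
  }
  if (weight == 0) return(new_dose_grid(dose, grid, provenance = "spot"))
  h <- grid$voxel_cm
  edges <- -grid$half + (0:n) * h
  sig <- lateral_sigma_cm(beam, geo$depth_phys)      # per z index
  # lateral window: voxels within 5 sigma_max of the axis
  wmax <- 5 * max(sig)
  ix <- which(grid$centers > x0 - wmax & grid$centers < x0 + wmax)
  iy <- which(grid$centers > y0 - wmax & grid$centers < y0 + wmax)
  if (!length(ix) || !length(iy)) return(new_dose_grid(dose, grid, "spot"))
  gx <- vapply(seq_len(n), function(iz)
    gauss_band(edges[ix], edges[ix + 1], x0, sig[iz]), numeric(length(ix)))
  gy <- vapply(seq_len(n), function(iz)
    gauss_band(edges[iy], edges[iy + 1], y0, sig[iz]), numeric(length(iy)))
  dim(gx) <- c(length(ix), n); dim(gy) <- c(length(iy), n)
  dd <- lut(energy_MeV)(geo$we_mid[ix, iy, , drop = FALSE])
  dim(dd) <- c(length(ix), length(iy), n)
  dep <- dd * geo$dwe[ix, iy, , drop = FALSE]        # MeV per proton
  lat <- array(0, dim = dim(dep))
  for (iz in seq_len(n)) lat[, , iz] <- outer(gx[, iz], gy[, iz])
  mass_kg <- geo$rho[ix, iy, , drop = FALSE] * h^3 * 1e-3
  dose[ix, iy, ] <- weight * dep * lat * .MEV_TO_J / mass_kg
  new_dose_grid(dose, grid, provenance = "spot")
}

# Influence computation used by the planner and scenario engine: per-spot
# dose (Gy per proton) at a fixed voxel subset, plus the quantities the
# emission model reuses (proton energy and fluence weights at Gd voxels).
# vox: data.frame(ix, iy, iz). Returns matrix [nvox x nspots].
spot_influence <- function(grid, spots, vox,
                           model = range_energy_model(),
                           beam = pencil_beam_model(),
                           geo = NULL, lut = NULL) {
  if (is.null(geo)) geo <- precompute_geometry(grid)
  if (is.null(lut)) lut <- lut_cache(model, beam)
  h <- grid$voxel_cm
  idx <- cbind(vox$ix, vox$iy, vox$iz)
  we <- geo$we_mid[idx]
  dwe <- geo$dwe[idx]
  rho <- geo$rho[idx]
  depth <- geo$depth_phys[vox$iz]
  sig <- lateral_sigma_cm(beam, depth)
  cx <- grid$centers[vox$ix]; cy <- grid$centers[vox$iy]
  xlo <- cx - h / 2; xhi <- cx + h / 2
  ylo <- cy - h / 2; yhi <- cy + h / 2
  mass_kg <- rho * h^3 * 1e-3
  A <- matrix(0, nrow(vox), nrow(spots))
  for (s in seq_len(nrow(spots))) {
    x0 <- spots$x_mm[s] / 10; y0 <- spots$y_mm[s] / 10
    g <- gauss_band(xlo, xhi, x0, sig) * gauss_band(ylo, yhi, y0, sig)
    A[, s] <- lut(spots$energy_MeV[s])(we) * dwe * g * .MEV_TO_J / mass_kg
  }
  A
}

new_dose_grid <- function(arr, grid, provenance = "cumulative",
                          uncertainty = NULL) {
  structure(list(dose = arr, voxel_mm = grid$voxel_cm * 10,
                 extent_cm = grid$extent, provenance = provenance,
                 uncertainty = uncertainty),
            class = "dose_grid")
}

#' Add two dose grids
#' @param e1,e2 `dose_grid` objects on the same mesh.
#' @export
`+.dose_grid` <- function(e1, e2) {
  stopifnot(identical(dim(e1$dose), dim(e2$dose)))
  structure(list(dose = e1$dose + e2$dose, voxel_mm = e1$voxel_mm,
                 extent_cm = e1$extent_cm, provenance = "cumulative",
                 uncertainty = NULL),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, %g mm voxels, max %.4g Gy, mean %.4g Gy\n",
              x$provenance, x$voxel_mm, max(x$dose), mean(x$dose)))
  invisible(x)
}

#' Write / read a dose grid (raw doubles + JSON sidecar)
#'
#' The array container is a flat stream of little-endian doubles in R's
#' column-major voxel order; the `.json` sidecar records dimensions, voxel
#' size and provenance.
#'
#' @param dg A `dose_grid`.
#' @param path Output path without extension (writes `path.bin`, `path.json`).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(dg, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(dg$dose), con, size = 8, endian = "little")
  jsonlite::write_json(list(dim = dim(dg$dose), voxel_mm = dg$voxel_mm,
                            extent_cm = dg$extent_cm,
                            provenance = dg$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  arr <- array(readBin(con, "double", n, size = 8, endian = "little"),
               dim = meta$dim)
  structure(list(dose = arr, voxel_mm = meta$voxel_mm,
                 extent_cm = meta$extent_cm, provenance = meta$provenance,
                 uncertainty = NULL), class = "dose_grid")
}
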