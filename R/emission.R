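#' Gd K-shell ionization / fluorescence model
#'
#' The ionization cross-section table spans 5-250 MeV protons and is
#' log-log interpolated. Published measurements for Gd reach only ~15 MeV;
#' above that the table is a modeled, monotone-increasing extension toward
#' the velocity-matching region (K-shell binding ~50 keV matches ~90 MeV
#' protons), shipped as a replaceable config default. Fluorescence yield
#' `omega_K = 0.93` and Kalpha1 branching `f_Kalpha1 = 0.48` are
#' literature-typical constants for Z = 64.
#'
#' @param sigma_table data.frame with `energy_MeV`, `sigma_barns` (monotone).
#' @param omega_K K fluorescence yield in (0, 1).
#' @param f_kalpha1 Kalpha1 fraction of K x-rays in (0, 1).
#' @return Object of class `kshell_model`.
#' @export
kshell_model <- function(sigma_table = NULL, omega_K = 0.93,
                         f_kalpha1 = 0.48) {
  if (is.null(sigma_table)) {
    sigma_table <- data.frame(
      energy_MeV  = c(5,    10,  15,  25, 40, 60, 90, 130, 180, 250),
      sigma_barns = c(0.05, 0.5, 1.5, 5,  14, 26, 42, 58,  70,  80)
    )
  }
  stopifnot(omega_K > 0, omega_K < 1, f_kalpha1 > 0, f_kalpha1 < 1,
            all(sigma_table$sigma_barns > 0),
            !is.unsorted(sigma_table$energy_MeV, strictly = TRUE),
            !is.unsorted(sigma_table$sigma_barns, strictly = TRUE))
  structure(list(sigma_table = sigma_table, omega_K = omega_K,
                 f_kalpha1 = f_kalpha1), class = "kshell_model")
}

#' K-shell ionization cross section (barns), log-log interpolated
#' @param E_MeV Proton energies (0 allowed; returns 0).
#' @param kshell A `kshell_model`.
#' @export
sigma_k <- function(E_MeV, kshell = kshell_model()) {
  tab <- kshell$sigma_table
  out <- numeric(length(E_MeV))
  pos <- E_MeV > 0
  if (any(pos)) {
    out[pos] <- exp(stats::approx(log(tab$energy_MeV), log(tab$sigma_barns),
                                  xout = log(pmin(pmax(E_MeV[pos],
                                                       min(tab$energy_MeV)),
                                                  max(tab$energy_MeV))),
                                  rule = 2)$y)
  }
  out
}

#' Secondary-neutron production and capture model
#'
#' Neutron yield per proton per cm of track scales as `(E/90)^2`, normalized
#' by `yield_90MeV`; thermalized transport to the Gd volume uses an isotropic
#' exponentially screened `1/(4 pi r^2)` kernel with diffusion length `L`.
#' 43 keV photons per capture combine the internal-conversion yield per
#' capture (0.5991), the fraction of IC vacancies in the K shell, the K
#' fluorescence yield and the Kalpha1 branching.
#'
#' @param yield_90MeV Neutrons per proton per cm at 90 MeV.
#' @param yield_exponent Energy scaling exponent.
#' @param diffusion_length_cm Thermal screening length L (cm).
#' @param ic_yield IC electrons per neutron capture in Gd.
#' @param k_vacancy_fraction Fraction of IC vacancies in the K shell.
#' @param kshell `kshell_model` supplying omega_K and f_Kalpha1.
#' @return Object of class `neutron_model`; field `photons_per_capture` holds
#'   the combined 43 keV photons-per-capture factor.
#' @export
neutron_model <- function(yield_90MeV = 2e-4, yield_exponent = 2,
                          diffusion_length_cm = 2.8, ic_yield = 0.5991,
                          k_vacancy_fraction = 0.8,
                          kshell = kshell_model()) {
  stopifnot(yield_90MeV >= 0, diffusion_length_cm > 0,
            ic_yield > 0, ic_yield < 1,
            k_vacancy_fraction > 0, k_vacancy_fraction <= 1)
  pi_x <- ic_yield * k_vacancy_fraction * kshell$omega_K * kshell$f_kalpha1
  structure(list(yield_90MeV = yield_90MeV,
                 yield_exponent = yield_exponent,
                 L = diffusion_length_cm,
                 ic_yield = ic_yield,
                 k_vacancy_fraction = k_vacancy_fraction,
                 photons_per_capture = pi_x), class = "neutron_model")
}

neutron_yield_per_cm <- function(E_MeV, neutron) {
  neutron$yield_90MeV * (pmax(E_MeV, 0) / 90)^neutron$yield_exponent
}

#' Residual proton energy at a water-equivalent depth
#'
#' `E(d) = energy_from_range(R(E0) - d)`, clamped at 0 beyond range;
#' strictly decreasing in depth.
#'
#' @param E0_MeV Beam energy at entry.
#' @param we_depth_cm Water-equivalent depth(s).
#' @param model A `range_energy_model`.
#' @export
energy_at_depth <- function(E0_MeV, we_depth_cm,
                            model = range_energy_model()) {
  R <- range_from_energy(E0_MeV, model)
  u <- pmax(R - we_depth_cm, 0)
  energy_from_range(u, model)
}

#' Residual proton energy of a spot at a voxel
#'
#' @param grid A `phantom_grid`.
#' @param spot One-row spot data.frame (`energy_MeV`, `x_mm`, `y_mm`).
#' @param voxel Length-3 voxel index (ix, iy, iz) on the spot's axis corridor.
#' @param model A `range_energy_model`.
#' @export
proton_energy_at <- function(grid, spot, voxel,
                             model = range_energy_model()) {
  geo <- precompute_geometry(grid)
  we <- geo$we_mid[voxel[1], voxel[2], voxel[3]]
  energy_at_depth(spot$energy_MeV, we, model)
}

# Data frame of target (Gd) voxels with everything the emission model needs.
target_voxel_table <- function(grid, geo = precompute_geometry(grid)) {
  idx <- which(geo$mask, arr.ind = TRUE)
  vox <- data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3])
  vox$cx <- grid$centers[vox$ix]
  vox$cy <- grid$centers[vox$iy]
  vox$cz <- grid$centers[vox$iz]
  vox$we_mid <- geo$we_mid[idx]
  vox$depth <- geo$depth_phys[vox$iz]
  vox
}

# Per-voxel expected PIXE 43 keV photons for one spot over the target voxel
# table. g = lateral Gaussian mass fraction per voxel.
pixe_per_voxel <- function(weight, E0, g, vox, grid, kshell, model, beam) {
  R <- range_from_energy(E0, model)
  E <- energy_at_depth(E0, vox$we_mid, model)
  phi <- weight * fluence_factor(beam, vox$we_mid, R) * g
  n_gd <- grid$target$gd_number_density
  phi * n_gd * sigma_k(E, kshell) * .BARN_CM2 * grid$voxel_cm *
    kshell$omega_K * kshell$f_kalpha1
}

#' Expected PIXE 43 keV photons emitted for one spot
#'
#' Sums, over the Gd voxels the beam crosses, the proton fluence through the
#' voxel (lateral Gaussian mass times surviving primaries) times the Gd
#' number density, the K-shell ionization cross section at the local proton
#' energy, the voxel path length, the fluorescence yield and the Kalpha1
#' branching. Linear in spot weight and in Gd concentration; zero if the
#' beam stops before the target.
#'
#' @param grid A `phantom_grid`.
#' @param spot One-row spot data.frame (`energy_MeV`, `x_mm`, `y_mm`,
#'   `weight_protons`).
#' @param kshell,model,beam Model components.
#' @return Expected emitted 43 keV photon count (scalar).
#' @export
pixe_yield <- function(grid, spot, kshell = kshell_model(),
                       model = range_energy_model(),
                       beam = pencil_beam_model()) {
  geo <- precompute_geometry(grid)
  vox <- target_voxel_table(grid, geo)
  if (nrow(vox) == 0 || grid$target$gd_number_density == 0) return(0)
  g <- lateral_mass(grid, vox, spot$x_mm, spot$y_mm, beam)
  sum(pixe_per_voxel(spot$weight_protons, spot$energy_MeV, g, vox, grid,
                     kshell, model, beam))
}

# Lateral Gaussian mass fraction of the spot through each voxel column cell.
lateral_mass <- function(grid, vox, x_mm, y_mm, beam) {
  h <- grid$voxel_cm
  sig <- lateral_sigma_cm(beam, vox$depth)
  gauss_band(vox$cx - h / 2, vox$cx + h / 2, x_mm / 10, sig) *
    gauss_band(vox$cy - h / 2, vox$cy + h / 2, y_mm / 10, sig)
}

# Neutron source strengths along the spot axis: data.frame(z, we, strength)
# with strength in neutrons (weight x yield/cm x cm).
capture_sources <- function(grid, spot, neutron, model, beam) {
  ray <- wepl_along_ray(grid, spot$x_mm, spot$y_mm)
  if (nrow(ray) == 0) return(data.frame(z = numeric(0), s = numeric(0)))
  R <- range_from_energy(spot$energy_MeV, model)
  E <- energy_at_depth(spot$energy_MeV, ray$we_mid_cm, model)
  s <- spot$weight_protons *
    fluence_factor(beam, ray$we_mid_cm, R) *
    neutron_yield_per_cm(E, neutron) * grid$voxel_cm
  data.frame(z = ray$z_cm, s = s)[E > 0, , drop = FALSE]
}

#' Screened isotropic transport kernel
#'
#' First-flight flux at distance `r` from an isotropic point source with
#' exponential removal over diffusion length `L`:
#' `exp(-r/L) / (4 pi r^2)` per cm^2. The Monte-Carlo analogue is a single
#' straight flight with exponentially distributed length of mean `L`; the
#' track-length estimator over a volume converges to the kernel's volume
#' integral.
#'
#' @param r_cm Distance(s) from the source (cm).
#' @param L_cm Diffusion (removal) length (cm).
#' @export
capture_kernel <- function(r_cm, L_cm) {
  stopifnot(L_cm > 0, all(r_cm > 0))
  exp(-r_cm / L_cm) / (4 * pi * r_cm^2)
}

# Per-voxel expected captures for one spot (vector over target voxel table).
capture_per_voxel <- function(grid, spot, vox, neutron, model, beam,
                              r_min_cm = 0.1) {
  src <- capture_sources(grid, spot, neutron, model, beam)
  nv <- nrow(vox)
  if (nrow(src) == 0 || nv == 0) return(numeric(nv))
  sigma_a <- macroscopic_capture_xs(grid$target)
  if (sigma_a == 0) return(numeric(nv))
  x0 <- spot$x_mm / 10; y0 <- spot$y_mm / 10
  rho2 <- (vox$cx - x0)^2 + (vox$cy - y0)^2
  dz2 <- outer(vox$cz, src$z, "-")^2
  r <- sqrt(rho2 + dz2)
  r <- pmax(r, r_min_cm)
  k <- capture_kernel(r, neutron$L)
  vvox <- grid$voxel_cm^3
  as.vector(k %*% src$s) * sigma_a * vvox
}

#' Expected capture-channel 43 keV photons emitted for one spot
#'
#' Neutron production along the proton track (yield ~ E^2, surviving
#' fluence), propagated with the screened isotropic kernel
#' `exp(-r/L) / (4 pi r^2)`, captured in the Gd voxels with the macroscopic
#' thermal cross section (optically thin target assumption), times the 43 keV
#' photons-per-capture factor. Linear in spot weight.
#'
#' @inheritParams pixe_yield
#' @param neutron A `neutron_model`.
#' @return Expected emitted 43 keV photon count (scalar).
#' @export
capture_yield <- function(grid, spot, neutron = neutron_model(),
                          model = range_energy_model(),
                          beam = pencil_beam_model()) {
  geo <- precompute_geometry(grid)
  vox <- target_voxel_table(grid, geo)
  if (nrow(vox) == 0) return(0)
  sum(capture_per_voxel(grid, spot, vox, neutron, model, beam)) *
    neutron$photons_per_capture
}

# Quasi-uniform unit directions (Fibonacci sphere), deterministic.
fibonacci_sphere <- function(M = 128) {
  i <- seq_len(M) - 0.5
  z <- 1 - 2 * i / M
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Distance to exit of an axis-aligned box [-half, half]^3 (or general
# lo/hi), from inside points. Vectorized over points for one direction.
.box_exit <- function(px, py, pz, u, lo, hi) {
  tx <- if (u[1] > 0) (hi[1] - px) / u[1] else if (u[1] < 0) (lo[1] - px) / u[1] else Inf
  ty <- if (u[2] > 0) (hi[2] - py) / u[2] else if (u[2] < 0) (lo[2] - py) / u[2] else Inf
  tz <- if (u[3] > 0) (hi[3] - pz) / u[3] else if (u[3] < 0) (lo[3] - pz) / u[3] else Inf
  pmin(tx, ty, pmin(tz, Inf))
}

# Entry/exit parameters of a ray with a box (slab method), vectorized over
# ray origins for one direction. Returns list(t1, t2).
.box_span <- function(px, py, pz, u, lo, hi) {
  t1 <- rep(-Inf, length(px)); t2 <- rep(Inf, length(px))
  p <- list(px, py, pz)
  for (a in 1:3) {
    if (u[a] == 0) {
      miss <- p[[a]] < lo[a] | p[[a]] > hi[a]
      t1[miss] <- Inf
    } else {
      ta <- (lo[a] - p[[a]]) / u[a]
      tb <- (hi[a] - p[[a]]) / u[a]
      t1 <- pmax(t1, pmin(ta, tb))
      t2 <- pmin(t2, pmax(ta, tb))
    }
  }
  list(t1 = t1, t2 = t2)
}

#' Mean escape survival of 43 keV photons per emission voxel
#'
#' For each emission voxel the exit path to the scoring sphere is averaged
#' over `M` fixed quasi-uniform directions; each path is attenuated by the
#' water and target-material thicknesses it crosses (vacuum outside the
#' phantom contributes nothing). Deterministic.
#'
#' @param grid A `phantom_grid`.
#' @param vox Target voxel table (from the internal geometry helpers); any
#'   data.frame with voxel centers `cx, cy, cz` in cm works.
#' @param sphere_radius_cm Scoring sphere inner radius; must enclose the
#'   phantom (>= half space diagonal).
#' @param M Number of directions.
#' @return Numeric vector of mean survival fractions in (0, 1].
#' @export
survival_map <- function(grid, vox, sphere_radius_cm = 8.7, M = 128) {
  if (sphere_radius_cm < grid$half * sqrt(3) - 1e-9) {
    stop("scoring sphere smaller than the phantom half-diagonal",
         call. = FALSE)
  }
  dirs <- fibonacci_sphere(M)
  mu_w <- grid$body$mu_43keV
  mu_t <- grid$target$mu_43keV
  off <- grid$target_offset_mm / 10
  lo_t <- off - grid$t_half; hi_t <- off + grid$t_half
  lo_p <- rep(-grid$half, 3); hi_p <- rep(grid$half, 3)
  surv <- numeric(nrow(vox))
  for (m in seq_len(M)) {
    u <- dirs[m, ]
    t_exit <- .box_exit(vox$cx, vox$cy, vox$cz, u, lo_p, hi_p)
    span <- .box_span(vox$cx, vox$cy, vox$cz, u, lo_t, hi_t)
    lt <- pmax(0, pmin(span$t2, t_exit) - pmax(span$t1, 0))
    surv <- surv + exp(-(mu_w * (t_exit - lt) + mu_t * lt))
  }
  surv / M
}

#' Expected detected counts from a per-voxel emission map
#'
#' @param emission Per-voxel expected emitted photons (same order as `vox`).
#' @inheritParams survival_map
#' @return Expected detected count (never exceeds the emitted total).
#' @export
detect <- function(emission, grid, vox, sphere_radius_cm = 8.7, M = 128) {
  sum(emission * survival_map(grid, vox, sphere_radius_cm, M))
}

#' Synthesize a secondary-photon spectrum
#'
#' Gaussian-broadened Gd lines (43 Kalpha, 49 Kbeta, 79.5 and 181.9 keV) over
#' a smooth exponential continuum, Poisson-sampled per bin; deterministic
#' given the seed. Line areas other than 43 keV are rendered at fixed
#' relative intensities (only the 43 keV line is analyzed quantitatively).
#'
#' @param area_43 Expected counts in the 43 keV line.
#' @param background_per_keV Expected continuum counts per keV at 0 keV
#'   (decays with constant 60 keV).
#' @param seed Integer seed.
#' @param fwhm_keV Detector line FWHM.
#' @param bin_keV Histogram bin width.
#' @param emax_keV Upper histogram edge.
#' @param relative_lines Named relative intensities of the catalog lines.
#' @return Object of class `spectrum_histogram`.
#' @export
synthesize_spectrum <- function(area_43, background_per_keV = 0, seed = 1,
                                fwhm_keV = 1, bin_keV = 0.5, emax_keV = 200,
                                relative_lines = c(`43` = 1, `49` = 0.27,
                                                   `79.5` = 0.15,
                                                   `181.9` = 0.08)) {
  edges <- seq(0, emax_keV, by = bin_keV)
  mids <- edges[-1] - bin_keV / 2
  sigma <- fwhm_keV / (2 * sqrt(2 * log(2)))
  lambda <- background_per_keV * bin_keV * exp(-mids / 60)
  for (ln in names(relative_lines)) {
    e0 <- as.numeric(ln)
    area <- area_43 * relative_lines[[ln]]
    lambda <- lambda + area * (stats::pnorm(edges[-1], e0, sigma) -
                                 stats::pnorm(edges[-length(edges)], e0, sigma))
  }
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  structure(list(edges = edges, mids = mids, counts = counts,
                 fwhm_keV = fwhm_keV,
                 lines = as.numeric(names(relative_lines)),
                 expected = lambda, seed = seed),
            class = "spectrum_histogram")
}

#' Sideband-subtracted net line area
#'
#' Net counts in a +-2 FWHM window around the line, with a flat background
#' estimated from equal-width sidebands on each side; the statistical error
#' is `sqrt(gross + background estimate)`.
#'
#' @param spectrum A `spectrum_histogram`.
#' @param line Line energy in keV (default 43).
#' @return List with `net`, `gross`, `background`, `error`.
#' @export
extract_line <- function(spectrum, line = 43) {
  f <- 2 * spectrum$fwhm_keV
  lo <- line - f; hi <- line + f
  if (lo < min(spectrum$edges) || hi > max(spectrum$edges)) {
    stop("line window outside the histogram support", call. = FALSE)
  }
  inw <- spectrum$mids >= lo & spectrum$mids <= hi
  side <- (spectrum$mids >= lo - f & spectrum$mids < lo) |
    (spectrum$mids > hi & spectrum$mids <= hi + f)
  gross <- sum(spectrum$counts[inw])
  bg <- if (any(side)) mean(spectrum$counts[side]) * sum(inw) else 0
  list(net = gross - bg, gross = gross, background = bg,
       error = sqrt(gross + bg))
}

#' @export
print.spectrum_histogram <- function(x, ...) {
  cat(sprintf("<spectrum_histogram> %d bins of %.2g keV, %g counts total\n",
              length(x$counts), diff(x$edges[1:2]), sum(x$counts)))
  cat("  line catalog (keV):", paste(x$lines, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spectrum_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "s", xlab = "energy (keV)",
                 ylab = "counts", ...)
  graphics::abline(v = x$lines, col = "grey70", lty = 3)
  invisible(x)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Deterministic substream seed below 2^31 from a master seed and stream ids.
substream_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}
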