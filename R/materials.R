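#' Mass fractions from a chemical formula
#'
#' Converts a named vector of stoichiometric counts (e.g. `c(C = 23, H = 42,
#' O = 13, N = 5, Gd = 1)` for gadoterate meglumine) into elemental mass
#' fractions.
#'
#' @param formula Named numeric vector of atom counts per formula unit.
#' @return Named numeric vector of mass fractions summing to one.
#' @export
element_fractions_from_formula <- function(formula) {
  stopifnot(is.numeric(formula), !is.null(names(formula)), all(formula > 0))
  el <- .elements_lookup(names(formula))
  mass <- el$A * as.numeric(formula)
  stats::setNames(mass / sum(mass), names(formula))
}

#' Molar mass of a chemical formula (g/mol)
#' @inheritParams element_fractions_from_formula
#' @export
molar_mass <- function(formula) {
  el <- .elements_lookup(names(formula))
  sum(el$A * as.numeric(formula))
}

#' Gadolinium number density of a Gd solution
#'
#' One Gd atom per gadoterate formula unit, so the nuclide number density is
#' the molar concentration times Avogadro's number.
#'
#' @param concentration_mmol_ml Gd concentration in mmol/mL.
#' @return Gd nuclei per cm^3.
#' @export
gd_number_density <- function(concentration_mmol_ml) {
  if (any(concentration_mmol_ml < 0)) {
    stop("gd concentration must be non-negative", call. = FALSE)
  }
  concentration_mmol_ml * 1e-3 * .AVOGADRO
}

#' Natural Gd isotope table
#'
#' Mass number, natural abundance and thermal-neutron capture cross section
#' (barns) for the seven stable gadolinium isotopes.
#' @return A data.frame, one row per isotope.
#' @export
gd_isotopes <- function() .GD_ISOTOPES

#' Abundance-weighted thermal capture cross section (barns)
#'
#' @param isotopes Data frame with columns `natural_abundance` and
#'   `thermal_capture_cross_section` (default: the shipped Gd table).
#' @return Weighted sum in barns (0 for an empty table).
#' @export
total_absorption_cross_section <- function(isotopes = gd_isotopes()) {
  if (NROW(isotopes) == 0) return(0)
  stopifnot(all(isotopes$thermal_capture_cross_section >= 0),
            sum(isotopes$natural_abundance) <= 1 + 1e-9)
  sum(isotopes$natural_abundance * isotopes$thermal_capture_cross_section)
}

# Bethe mass stopping power (MeV cm^2/g) for protons at kinetic energy E_MeV
# in a mixture given by elemental mass fractions. Shell/density corrections
# are omitted: only the water-normalized ratio (RSP) is consumed downstream.
bethe_mass_stopping <- function(E_MeV, fractions) {
  el <- .elements_lookup(names(fractions))
  gamma <- 1 + E_MeV / .PROTON_MC2
  beta2 <- 1 - 1 / gamma^2
  arg <- 2 * .ELECTRON_MC2 * 1e6 * beta2 * gamma^2 # eV
  L <- log(outer(arg, el$I_eV, "/")) - beta2       # [length(E) x n_el]
  drop(L %*% (as.numeric(fractions) * el$Z / el$A)) * .BETHE_K / beta2
}

.WATER_FRACTIONS <- c(H = 2 * 1.008, O = 15.999) / (2 * 1.008 + 15.999)

#' Construct a material
#'
#' A material carries a density, elemental mass fractions, an optional Gd
#' concentration, its relative stopping power (Bragg additivity of Bethe mass
#' stopping powers at the 80 MeV reference energy, normalized to water) and
#' its 43 keV linear attenuation coefficient (elemental mass attenuation
#' mixture rule, or `ln(2)/hvl_43keV` when an HVL override is given).
#'
#' @param name Material name.
#' @param density_g_cm3 Mass density in g/cm^3.
#' @param composition Named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-9).
#' @param gd_concentration_mmol_ml Gd concentration (0 for Gd-free materials).
#' @param hvl_43keV Optional half-value-layer override at 43 keV, in cm
#'   (use `Inf` for vacuum-like entries).
#' @return An object of class `material`.
#' @export
material <- function(name, density_g_cm3, composition,
                     gd_concentration_mmol_ml = 0, hvl_43keV = NULL) {
  stopifnot(density_g_cm3 > 0, gd_concentration_mmol_ml >= 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", sum(composition), ")",
         call. = FALSE)
  }
  el <- .elements_lookup(names(composition))
  mu <- if (is.null(hvl_43keV)) {
    density_g_cm3 * sum(as.numeric(composition) * el$mu_rho_43)
  } else {
    mu_from_hvl(hvl_43keV)
  }
  out <- structure(list(
    name = name,
    density = density_g_cm3,
    composition = composition,
    gd_concentration = gd_concentration_mmol_ml,
    gd_number_density = gd_number_density(gd_concentration_mmol_ml),
    mu_43keV = mu
  ), class = "material")
  out$relative_stopping_power <- relative_stopping_power(out)
  out
}

#' Relative (to water) proton stopping power of a material
#'
#' Bragg additivity of elemental Bethe mass stopping powers at a reference
#' energy, times the density ratio to water. Water evaluates to exactly 1.
#'
#' @param mat A `material`.
#' @param reference_energy_MeV Reference proton energy (default 80 MeV).
#' @return Dimensionless RSP.
#' @export
relative_stopping_power <- function(mat, reference_energy_MeV = 80) {
  s_mat <- bethe_mass_stopping(reference_energy_MeV, mat$composition)
  s_w <- bethe_mass_stopping(reference_energy_MeV, .WATER_FRACTIONS)
  mat$density * s_mat / (1.0 * s_w)
}

#' Linear attenuation coefficient from a half-value layer
#'
#' @param hvl_cm Half-value layer in cm (`Inf` for vacuum).
#' @return mu in cm^-1 (`ln 2 / HVL`).
#' @export
mu_from_hvl <- function(hvl_cm) {
  if (any(hvl_cm <= 0)) stop("HVL must be positive", call. = FALSE)
  log(2) / hvl_cm
}

#' Photon survival fraction along an attenuating path
#'
#' @param length_cm Path length(s) in cm.
#' @param mu_cm Matching linear attenuation coefficient(s) in cm^-1.
#' @return `exp(-sum(mu * length))`.
#' @export
attenuation_survival <- function(length_cm, mu_cm) {
  exp(-sum(mu_cm * length_cm))
}

#' Water material
#' @return A `material` (RSP exactly 1, 43 keV HVL about 2.6 cm).
#' @export
water_material <- function() {
  material("water", 1.0, .WATER_FRACTIONS)
}

#' Dotarem material (gadoterate meglumine in water)
#'
#' Composition is derived from the C23H42O13N5Gd empirical formula at the
#' given molar concentration, with water as solvent, at the stated total
#' solution density (1.1753 g/cm^3 for the commercial 0.5 mmol/mL agent).
#' The concentration is a knob for concentration-scaling studies.
#'
#' @param concentration_mmol_ml Gd (= gadoterate) concentration in mmol/mL.
#' @param density_g_cm3 Total solution density.
#' @return A `material`.
#' @export
dotarem_material <- function(concentration_mmol_ml = 0.5,
                             density_g_cm3 = 1.1753) {
  if (concentration_mmol_ml == 0) {
    m <- material("dotarem-0", density_g_cm3, .WATER_FRACTIONS, 0)
    return(m)
  }
  mm <- molar_mass(.GADOTERATE_FORMULA)
  gado_g <- concentration_mmol_ml * 1e-3 * mm        # g of solute per cm^3
  if (gado_g >= density_g_cm3) {
    stop("solute mass exceeds solution density", call. = FALSE)
  }
  w_gado <- gado_g / density_g_cm3
  f_gado <- element_fractions_from_formula(.GADOTERATE_FORMULA)
  syms <- union(names(f_gado), names(.WATER_FRACTIONS))
  comp <- stats::setNames(numeric(length(syms)), syms)
  comp[names(f_gado)] <- comp[names(f_gado)] + w_gado * f_gado
  comp[names(.WATER_FRACTIONS)] <- comp[names(.WATER_FRACTIONS)] +
    (1 - w_gado) * .WATER_FRACTIONS
  material("dotarem", density_g_cm3, comp, concentration_mmol_ml)
}

#' Macroscopic thermal capture cross section of a material (cm^-1)
#'
#' `Sigma_a = n_Gd x sigma_total`, with the abundance-weighted microscopic
#' cross section of the shipped isotope table.
#'
#' @param mat A `material`.
#' @param isotopes Isotope table (default shipped Gd table).
#' @export
macroscopic_capture_xs <- function(mat, isotopes = gd_isotopes()) {
  mat$gd_number_density * total_absorption_cross_section(isotopes) * .BARN_CM2
}

#' 43 keV attenuation entries for discussion tissues
#'
#' Half-value layers at 43 keV for water, lung, air and bone (ranges for the
#' heterogeneous tissues), with the corresponding linear attenuation
#' coefficients. Shipped for attenuation sensitivity studies only; no
#' heterogeneous geometries are modeled.
#'
#' @return data.frame with columns `tissue`, `hvl_lo_cm`, `hvl_hi_cm`,
#'   `mu_lo_cm`, `mu_hi_cm`.
#' @export
attenuation_table <- function() {
  tab <- data.frame(
    tissue    = c("water", "lung", "air", "bone"),
    hvl_lo_cm = c(2.6, 2.45, 2314, 0.54),
    hvl_hi_cm = c(2.6, 2.90, 2765, 0.85)
  )
  tab$mu_lo_cm <- mu_from_hvl(tab$hvl_hi_cm)
  tab$mu_hi_cm <- mu_from_hvl(tab$hvl_lo_cm)
  tab
}

#' Materials from a config list or YAML file
#'
#' Each entry is a key-value map with fields `name`, `density`, and either
#' `formula` (named atom counts) or `fractions` (named mass fractions), plus
#' optional `gd_concentration` (mmol/mL) and `hvl_43keV` (cm) override.
#'
#' @param config A list of material entries, or a path to a YAML file holding
#'   one.
#' @return Named list of `material` objects.
#' @export
materials_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- lapply(config, function(m) {
    comp <- if (!is.null(m$formula)) {
      element_fractions_from_formula(unlist(m$formula))
    } else {
      unlist(m$fractions)
    }
    material(m$name, m$density, comp,
             gd_concentration_mmol_ml = m$gd_concentration %||% 0,
             hvl_43keV = m$hvl_43keV)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s\n", x$name))
  cat(sprintf("  density: %.4f g/cm^3   RSP: %.4f   mu(43 keV): %.4f cm^-1\n",
              x$density, x$relative_stopping_power, x$mu_43keV))
  if (x$gd_concentration > 0) {
    cat(sprintf("  Gd: %.3g mmol/mL  (%.4g nuclei/cm^3, Sigma_a = %.3f cm^-1)\n",
                x$gd_concentration, x$gd_number_density,
                macroscopic_capture_xs(x)))
  }
  comp <- paste(sprintf("%s %.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}
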