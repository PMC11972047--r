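# Embedded physical constants and small element tables.
#
# Elemental data are limited to the elements occurring in the shipped
# materials (H, C, N, O, Gd).  Mean excitation energies I follow ICRU-37
# elemental recommendations; 43 keV mass attenuation coefficients are
# interpolated from the NIST XCOM elemental tables (Gd evaluated just below
# its 50.24 keV K edge).  Values are package constants, not downloads.

.AVOGADRO <- 6.02214076e23   # mol^-1
.MEV_TO_J <- 1.602176634e-13 # J per MeV
.BARN_CM2 <- 1e-24           # cm^2 per barn
.PROTON_MC2 <- 938.272       # MeV
.ELECTRON_MC2 <- 0.510999    # MeV
.BETHE_K <- 0.307075         # MeV cm^2 / g (4 pi N_A r_e^2 m_e c^2)

.ELEMENTS <- data.frame(
  symbol    = c("H",   "C",    "N",    "O",    "Gd"),
  Z         = c(1,      6,      7,      8,      64),
  A         = c(1.008, 12.011, 14.007, 15.999, 157.25),
  I_eV      = c(19.2,  78.0,   82.0,   95.0,   591.0),
  mu_rho_43 = c(0.346, 0.208,  0.227,  0.257,  3.10),  # cm^2/g at 43 keV
  stringsAsFactors = FALSE
)

# Natural gadolinium isotopes.  Thermal (2200 m/s) capture cross sections in
# barns; only Gd-155 and Gd-157 are non-negligible.  Abundances for 155/157
# are 0.148 / 0.157 (Gd-156 trimmed by 5e-4 so the table sums to one).
.GD_ISOTOPES <- data.frame(
  mass_number                   = c(152,    154,    155,    156,    157,    158,    160),
  natural_abundance             = c(0.0020, 0.0218, 0.1480, 0.2042, 0.1570, 0.2484, 0.2186),
  thermal_capture_cross_section = c(735,    85,     60900,  1.5,    254000, 2.2,    0.77)
)

# Gadoterate meglumine, the active compound of the Dotarem contrast agent.
.GADOTERATE_FORMULA <- c(C = 23, H = 42, O = 13, N = 5, Gd = 1)

.elements_lookup <- function(symbols) {
  idx <- match(symbols, .ELEMENTS$symbol)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(symbols[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  .ELEMENTS[idx, , drop = FALSE]
}
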