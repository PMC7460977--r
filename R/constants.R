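# Physical constants (CODATA 2018). Energies are eV throughout the package;
# lengths Angstrom; frequencies cm^-1 at the user surface.
.const <- list(
  hbar_eVs   = 6.582119569e-16,   # reduced Planck constant, eV s
  kB_eVK     = 8.617333262e-5,    # Boltzmann constant, eV/K
  e_C        = 1.602176634e-19,   # elementary charge, C (also J per eV)
  amu_kg     = 1.66053906660e-27, # atomic mass unit, kg
  c_cms      = 2.99792458e10,     # speed of light, cm/s
  hc_eVcm    = 1.239841984e-4     # h*c, eV cm (hbar*omega = hc * wavenumber)
)

#' Thermal energy k_B T
#'
#' @param T temperature in kelvin.
#' @return `k_B T` in eV (numerically equal to `k_B T / e` in volts).
#' @examples
#' kBT(300) * 1000  # ~25.9 meV at room temperature
#' @export
kBT <- function(T) {
  stopifnot(is.numeric(T), all(T > 0))
  .const$kB_eVK * T
}

# lambda_i [eV] = 0.5 * omega_SI^2 * dq_SI^2 / e with omega from cm^-1 and
# dq from amu^(1/2) A. Collapsed into one factor:
#   0.5 * (2 pi c)^2 * amu * 1e-20 / e  ~  1.836e-6 eV per (cm^-1)^2 (amu A^2)
.lambda_conv <- 0.5 * (2 * pi * .const$c_cms)^2 * .const$amu_kg * 1e-20 /
  .const$e_C

# mode force constant kappa [eV/(amu A^2)] -> wavenumber [cm^-1]
.kappa_to_wavenumber <- function(kappa) {
  omega_si <- sqrt(kappa * .const$e_C / (.const$amu_kg * 1e-20))
  omega_si / (2 * pi * .const$c_cms)
}
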