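# Physical constants used throughout. Units are the package's working units:
# energies in eV, rates in s^-1, times in ps (traces) or s (kinetics),
# distances in Angstrom, charges in units of e, potentials in V.

#' Physical constants
#'
#' Constants fixed by the package: `kB_eV` is the Boltzmann constant in
#' eV/K (CODATA, 8.617333262e-5), `ke_VA` the Coulomb constant in
#' V*Angstrom/e (14.399645), `c_cm_s` the speed of light in cm/s, and
#' `THz_to_cm1` the conversion from THz to wavenumbers
#' (1 THz = 33.35641 cm^-1).
#'
#' @format A named list with elements `kB_eV`, `ke_VA`, `c_cm_s`,
#'   `THz_to_cm1`.
#' @export
ht_constants <- list(
  kB_eV     = 8.617333262e-5,
  ke_VA     = 14.399645,
  c_cm_s    = 2.99792458e10,
  THz_to_cm1 = 1e12 / 2.99792458e10
)
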