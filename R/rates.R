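#' Rate-constant set for the hole-transfer kinetic scheme
#'
#' Bundles every parameter of the four-step hole-transfer mechanism: the
#' activation prefactor `k_act0` (the rate at which solvent and counterion
#' motion brings two iso-energetic hole sites into vibronic resonance), the
#' in-situ hole site-energy differences `dE_DA` (donor to acceptor) and
#' `dE_AD` (acceptor to donor) entering the Arrhenius activation law, the
#' solvent relaxation rates `k_rel_D`/`k_rel_A` that return a resonant
#' ensemble to a charge-localized equilibrium, the resonant tunneling rate
#' `k_HT` (symmetric by microscopic reversibility in resonance), and the
#' damage (guanine radical-cation deprotonation) rates `k_dam_D`/`k_dam_A`.
#'
#' Defaults follow the literature values for guanine oxidation kinetics:
#' solvent relaxation at 1e13 s^-1, deprotonation of G radical cations at
#' 1e7 s^-1 and of stacked GG/GGG cations at 3e6 s^-1, temperature 300 K.
#' The default reverse site-energy difference `dE_AD = 0.3` eV represents a
#' deep GGG trap, making reverse activation negligible at room temperature.
#'
#' @param k_act0 Activation prefactor, s^-1.
#' @param dE_DA,dE_AD Hole site-energy differences for forward (donor to
#'   acceptor) and reverse activation, eV. Only uphill (positive) values
#'   attenuate the rate; see [arrhenius_activation()].
#' @param k_rel_D,k_rel_A Solvent relaxation rates, s^-1.
#' @param k_HT Resonant hole-tunneling rate, s^-1.
#' @param k_dam_D,k_dam_A Damage (deprotonation) rates at the donor and
#'   acceptor sites, s^-1.
#' @param temperature Temperature, K.
#'
#' @return An object of class `rate_set` (a validated named list).
#' @seealso [build_scheme()], [read_rates_json()]
#' @examples
#' rs <- rate_set(k_act0 = 1e10, k_HT = 6e12)
#' rs
#' @export
rate_set <- function(k_act0 = 1e10, dE_DA = 0, dE_AD = 0.3,
                     k_rel_D = 1e13, k_rel_A = 1e13,
                     k_HT = 0, k_dam_D = 1e7, k_dam_A = 3e6,
                     temperature = 300) {
  for (nm in c("k_act0", "k_rel_D", "k_rel_A", "k_HT", "k_dam_D", "k_dam_A")) {
    stopifnot_scalar_number(get(nm), nm, nonnegative = TRUE)
  }
  # dE = +Inf expresses an exactly closed (infinitely uphill) channel
  stopifnot_scalar_number(dE_DA, "dE_DA", allow_inf = TRUE)
  stopifnot_scalar_number(dE_AD, "dE_AD", allow_inf = TRUE)
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  structure(
    list(k_act0 = k_act0, dE_DA = dE_DA, dE_AD = dE_AD,
         k_rel_D = k_rel_D, k_rel_A = k_rel_A, k_HT = k_HT,
         k_dam_D = k_dam_D, k_dam_A = k_dam_A, temperature = temperature),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Hole-transfer rate set (s^-1 unless noted):\n")
  cat(sprintf("  k_act0  %.4g    dE_DA %.4g eV    dE_AD %.4g eV\n",
              x$k_act0, x$dE_DA, x$dE_AD))
  cat(sprintf("  k_rel_D %.4g    k_rel_A %.4g    k_HT %.4g\n",
              x$k_rel_D, x$k_rel_A, x$k_HT))
  cat(sprintf("  k_dam_D %.4g    k_dam_A %.4g    T %.4g K\n",
              x$k_dam_D, x$k_dam_A, x$temperature))
  invisible(x)
}

#' Arrhenius-activated resonance rate
#'
#' Rate of the solvent-driven activation step that brings donor and acceptor
#' hole levels into vibronic resonance:
#' \deqn{k_{act} = k_{act}^0(T) \exp(-\max(0, \Delta E) / k_B T).}
#' Only uphill site-energy differences attenuate the rate: seeking resonance
#' cannot be faster than the solvent-limited prefactor, so a downhill
#' (negative) `dE` returns `k_act0` unchanged.
#'
#' @param k_act0 Prefactor, s^-1 (rate for iso-energetic sites).
#' @param dE Hole site-energy difference toward the target site, eV.
#' @param temperature Temperature, K.
#' @return Activation rate, s^-1.
#' @examples
#' arrhenius_activation(1e10, 0, 300)            # = prefactor
#' arrhenius_activation(1e10, 0.025852, 300)     # barrier of kB*T: k0/e
#' @export
arrhenius_activation <- function(k_act0, dE, temperature = 300) {
  stopifnot_scalar_number(k_act0, "k_act0", nonnegative = TRUE)
  stopifnot_scalar_number(dE, "dE", allow_inf = TRUE)
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  k_act0 * exp(-max(0, dE) / (ht_constants$kB_eV * temperature))
}

#' Read a rate-constant set from JSON
#'
#' Reads a JSON rate configuration into a [rate_set()]. The activation
#' prefactor may be given either directly (`"k_act0"`, s^-1) or as an
#' activation time (`"tau_act_ps"`, ps), in which case
#' `k_act0 = 1/tau_act` with no further decomposition. Site-energy
#' differences use keys `"dE_DA_eV"`/`"dE_AD_eV"`; remaining keys match the
#' [rate_set()] arguments with `"temperature_K"` for the temperature.
#' Missing entries fall back to the [rate_set()] defaults (relaxation
#' 1e13 s^-1, damage 1e7 and 3e6 s^-1).
#'
#' @param path Path to a JSON file.
#' @return A [rate_set()].
#' @export
read_rates_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) {
    ht_error("ht_parse_error", sprintf("'%s': expected a JSON object", path))
  }
  known <- c("k_act0", "tau_act_ps", "dE_DA_eV", "dE_AD_eV", "k_rel_D",
             "k_rel_A", "k_HT", "k_dam_D", "k_dam_A", "temperature_K")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    ht_error("ht_parse_error",
             sprintf("'%s': unknown rate key(s): %s", path,
                     paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$tau_act_ps)) {
    if (!is.null(cfg$k_act0)) {
      ht_error("ht_parse_error",
               sprintf("'%s': give either k_act0 or tau_act_ps, not both", path))
    }
    cfg$k_act0 <- 1 / (cfg$tau_act_ps * 1e-12)
    cfg$tau_act_ps <- NULL
  }
  args <- list()
  map <- c(k_act0 = "k_act0", dE_DA_eV = "dE_DA", dE_AD_eV = "dE_AD",
           k_rel_D = "k_rel_D", k_rel_A = "k_rel_A", k_HT = "k_HT",
           k_dam_D = "k_dam_D", k_dam_A = "k_dam_A",
           temperature_K = "temperature")
  for (key in names(cfg)) args[[map[[key]]]] <- cfg[[key]]
  do.call(rate_set, args)
}
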