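#' Stationary Ornstein-Uhlenbeck noise series
#'
#' Generates a stationary OU sequence by the exact discretization
#' `x[t+1] = x[t] * exp(-dt/tau_c) + sigma * sqrt(1 - exp(-2 dt/tau_c)) * xi`,
#' with `x[1] ~ N(0, sigma^2)`, so the sample path has exactly the OU
#' stationary variance `sigma^2` and lag-one autocorrelation
#' `exp(-dt/tau_c)` at any step size (no Euler discretization bias). This
#' is the noise model for solvent-driven site-energy fluctuations.
#'
#' @param n Number of samples.
#' @param dt Sampling interval (same unit as `tau_c`).
#' @param sigma Stationary standard deviation.
#' @param tau_c Correlation time (> 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- ou_process(1000, 0.5, 0.15, 10, seed = 1)
#' sd(x)   # near 0.15
#' @export
ou_process <- function(n, dt, sigma, tau_c, seed = NULL) {
  stopifnot_scalar_number(n, "n", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma", nonnegative = TRUE)
  stopifnot_scalar_number(tau_c, "tau_c", positive = TRUE)
  n <- as.integer(n)
  if (sigma == 0) return(numeric(n))
  with_preserved_seed(seed, {
    rho <- exp(-dt / tau_c)
    innov_sd <- sigma * sqrt(1 - rho^2)
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sigma)
    xi <- rnorm(n - 1L)
    for (i in seq_len(n - 1L)) x[i + 1L] <- x[i] * rho + innov_sd * xi[i]
    x
  })
}

#' Configuration for synthetic trajectory signals
#'
#' Defaults emulate the study conditions of the MD/QM-MM trajectories the
#' analysis targets: 2 ns of 0.5 ps-sampled site energies, an initial
#' donor-acceptor gap of -2.0 eV closing linearly and clamping at zero
#' (equalization at 800 ps for the default slope), stationary OU
#' fluctuations of 0.15 eV with a 10 ps correlation time on the gap, and 3
#' replicate simulations. For potential-like signals, fs-scale sampling and
#' harmonic components in the 100-3000 cm^-1 vibrational band are
#' configured instead.
#'
#' @param duration_ps Record length, ps (default 2000).
#' @param dt_ps Sampling interval, ps (default 0.5; use ~1e-3 for
#'   potential signals).
#' @param gap0_eV Initial donor-acceptor gap, eV (default -2.0; negative =
#'   hole stabilized on the donor).
#' @param slope_eV_ps Linear gap drift, eV/ps. Default `NULL` derives the
#'   slope from `t_eq_ps`.
#' @param t_eq_ps Target equalization time, ps (default 800); used when
#'   `slope_eV_ps` is `NULL`.
#' @param sigma_eV Stationary SD of the *gap* fluctuation, eV (default
#'   0.15). Each energy channel receives independent OU noise at
#'   `sigma_eV / sqrt(2)` so their difference has SD `sigma_eV`. For
#'   single-channel potential signals `sigma_eV` is the signal SD (in V).
#' @param tau_c_ps OU correlation time, ps (default 10).
#' @param donor_level_eV,acceptor_level_eV Baseline HOMO levels, eV
#'   (defaults -7 and -5: the donor starts `gap0_eV` below the acceptor).
#' @param common_mode_sigma_eV Optional extra OU noise shared by both
#'   channels (common-mode solvent; cancels exactly in the gap; default 0).
#' @param level Mean level of a potential-like signal, V (default 0).
#' @param harmonics `data.frame(wavenumber_cm1, amplitude)` of cosine
#'   components for potential-like signals (optional `phase` column,
#'   radians; missing phases are drawn uniformly).
#' @param n_replicates Number of replicate simulations (default 3).
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return A `trace_config` list.
#' @export
trace_config <- function(duration_ps = 2000, dt_ps = 0.5, gap0_eV = -2.0,
                         slope_eV_ps = NULL, t_eq_ps = 800,
                         sigma_eV = 0.15, tau_c_ps = 10,
                         donor_level_eV = -7, acceptor_level_eV = -5,
                         common_mode_sigma_eV = 0,
                         level = 0, harmonics = NULL,
                         n_replicates = 3, seed = 20210910) {
  stopifnot_scalar_number(duration_ps, "duration_ps", positive = TRUE)
  stopifnot_scalar_number(dt_ps, "dt_ps", positive = TRUE)
  stopifnot_scalar_number(sigma_eV, "sigma_eV", nonnegative = TRUE)
  stopifnot_scalar_number(tau_c_ps, "tau_c_ps", positive = TRUE)
  stopifnot_scalar_number(n_replicates, "n_replicates", positive = TRUE)
  if (is.null(slope_eV_ps)) {
    stopifnot_scalar_number(t_eq_ps, "t_eq_ps", positive = TRUE)
    slope_eV_ps <- -gap0_eV / t_eq_ps
  }
  if (!is.null(harmonics)) {
    harmonics <- as.data.frame(harmonics)
    if (!all(c("wavenumber_cm1", "amplitude") %in% names(harmonics))) {
      ht_error("ht_config_error",
               "harmonics needs columns wavenumber_cm1 and amplitude")
    }
  }
  structure(
    list(duration_ps = duration_ps, dt_ps = dt_ps, gap0_eV = gap0_eV,
         slope_eV_ps = slope_eV_ps, sigma_eV = sigma_eV,
         tau_c_ps = tau_c_ps, donor_level_eV = donor_level_eV,
         acceptor_level_eV = acceptor_level_eV,
         common_mode_sigma_eV = common_mode_sigma_eV,
         level = level, harmonics = harmonics,
         n_replicates = as.integer(n_replicates), seed = seed),
    class = "trace_config"
  )
}

config_times <- function(config) {
  seq(0, config$duration_ps - config$dt_ps / 2, by = config$dt_ps)
}

#' Synthetic donor/acceptor site-energy trajectory
#'
#' Builds one replicate of a two-channel site-energy trace with the
#' structure the analysis pipeline assumes: deterministic drifts whose
#' difference follows the configured linear ramp (starting at `gap0_eV`,
#' clamped at zero after the crossing so the levels stay degenerate for the
#' rest of the record) plus independent stationary OU noise on each
#' channel. Replicate `r` is a pure function of `(config, r)`: its seed is
#' `config$seed + r - 1`, so replicates 1..n use base seed + 0, 1, ....
#'
#' @param config A [trace_config()].
#' @param replicate Replicate index (1-based).
#' @return A two-channel [site_energy_trace()].
#' @examples
#' tr <- generate_gap_trace(trace_config(sigma_eV = 0), replicate = 1)
#' gap <- gap_trace(tr)
#' min(tr$time_ps[gap$gap_eV >= 0])   # crosses zero at 800 ps
#' @export
generate_gap_trace <- function(config, replicate = 1L) {
  if (!inherits(config, "trace_config")) {
    ht_error("ht_invalid_parameter", "`config` must come from trace_config()")
  }
  stopifnot_scalar_number(replicate, "replicate", positive = TRUE)
  t <- config_times(config)
  n <- length(t)
  ramp <- pmin(0, config$gap0_eV + config$slope_eV_ps * t)
  seed <- config$seed + as.integer(replicate) - 1L
  ch_sigma <- config$sigma_eV / sqrt(2)
  noise <- with_preserved_seed(seed, {
    nd <- ou_process(n, config$dt_ps, ch_sigma, config$tau_c_ps)
    na <- ou_process(n, config$dt_ps, ch_sigma, config$tau_c_ps)
    nc <- if (config$common_mode_sigma_eV > 0) {
      ou_process(n, config$dt_ps, config$common_mode_sigma_eV, config$tau_c_ps)
    } else numeric(n)
    list(d = nd, a = na, c = nc)
  })
  site_energy_trace(
    t,
    e_donor = config$acceptor_level_eV + ramp + noise$d + noise$c,
    e_acceptor = config$acceptor_level_eV + noise$a + noise$c,
    replicate = as.integer(replicate)
  )
}

#' Synthetic fs-sampled potential-like signal
#'
#' Mean level plus a sum of cosine harmonics (wavenumbers in cm^-1,
#' amplitudes in signal units, phases fixed or random) plus OU noise —
#' designed so that [fourier_spectrum()] recovers the planted band. Any
#' harmonic at or above the Nyquist wavenumber `1 / (2 dt c)` is a
#' configuration error.
#'
#' @param config A [trace_config()] with fs-scale `dt_ps` and a
#'   `harmonics` table.
#' @param seed Seed (default `config$seed`).
#' @return A single-channel [site_energy_trace()] (channel
#'   `"potential_V"`).
#' @examples
#' cfg <- trace_config(duration_ps = 1, dt_ps = 1e-3, sigma_eV = 0,
#'                     harmonics = data.frame(wavenumber_cm1 = 740,
#'                                            amplitude = 1, phase = 0))
#' sig <- generate_potential_signal(cfg)
#' @export
generate_potential_signal <- function(config, seed = config$seed) {
  if (!inherits(config, "trace_config")) {
    ht_error("ht_invalid_parameter", "`config` must come from trace_config()")
  }
  t <- config_times(config)
  n <- length(t)
  dt_s <- config$dt_ps * 1e-12
  nyquist_cm1 <- 1 / (2 * dt_s * ht_constants$c_cm_s)
  h <- config$harmonics
  if (!is.null(h) && nrow(h) && any(h$wavenumber_cm1 >= nyquist_cm1)) {
    ht_error("ht_config_error",
             sprintf("harmonic at/above the Nyquist wavenumber %.4g cm^-1",
                     nyquist_cm1))
  }
  with_preserved_seed(seed, {
    x <- rep(config$level, n)
    if (!is.null(h) && nrow(h)) {
      phases <- if ("phase" %in% names(h)) h$phase
                else runif(nrow(h), 0, 2 * pi)
      for (i in seq_len(nrow(h))) {
        freq_hz <- h$wavenumber_cm1[i] * ht_constants$c_cm_s
        x <- x + h$amplitude[i] * cos(2 * pi * freq_hz * t * 1e-12 + phases[i])
      }
    }
    if (config$sigma_eV > 0) {
      x <- x + ou_process(n, config$dt_ps, config$sigma_eV, config$tau_c_ps)
    }
    site_energy_trace(t, value = x, channel = "potential_V")
  })
}

#' Configuration for toy point-charge snapshot trajectories
#'
#' Describes a toy solvated system: a fixed solute (a few point charges
#' grouped into named sites standing in for the probed nucleobase stacks)
#' surrounded by water-like point dipoles — two opposite fractional charges
#' at fixed separation — whose orientations random-walk from frame to
#' frame. Each dipole is exactly neutral.
#'
#' @param box_A Cubic box edge, Angstrom (default 25).
#' @param n_dipoles Number of water-like dipoles (default 60).
#' @param dipole_charge_e Magnitude of each dipole's partial charges, e
#'   (default 0.417, a water-like value).
#' @param dipole_sep_A Charge-charge separation, Angstrom (default
#'   0.9572).
#' @param reorient_sd Per-frame SD of the Gaussian orientation kick
#'   (default 0.15; 0 freezes the solvent).
#' @param polarization Strength (0-1) of the solvation bias pulling each
#'   dipole's negative end toward the solute's positive charge centroid
#'   (default 0.4). This emulates the oriented hydration shell around a
#'   cation, giving the probed sites the negative mean potential a
#'   stabilized hole experiences; 0 gives an unpolarized solvent.
#' @param solute `data.frame(x, y, z, q, site)` of fixed solute charges;
#'   the default places a +1 e three-atom "G3prime" cluster and a neutral
#'   nine-atom "GGG" stack ~7 Angstrom apart near the box center.
#' @param seed Base seed.
#' @return A `snapshot_config` list.
#' @export
snapshot_config <- function(box_A = 25, n_dipoles = 60,
                            dipole_charge_e = 0.417, dipole_sep_A = 0.9572,
                            reorient_sd = 0.15, polarization = 0.4,
                            solute = NULL, seed = 20210910) {
  stopifnot_scalar_number(box_A, "box_A", positive = TRUE)
  stopifnot_scalar_number(n_dipoles, "n_dipoles", nonnegative = TRUE)
  stopifnot_scalar_number(dipole_charge_e, "dipole_charge_e",
                          nonnegative = TRUE)
  stopifnot_scalar_number(dipole_sep_A, "dipole_sep_A", positive = TRUE)
  stopifnot_scalar_number(reorient_sd, "reorient_sd", nonnegative = TRUE)
  stopifnot_scalar_number(polarization, "polarization", nonnegative = TRUE)
  if (polarization > 1) {
    ht_error("ht_config_error", "polarization must be in [0, 1]")
  }
  if (is.null(solute)) solute <- default_toy_solute(box_A)
  solute <- as.data.frame(solute)
  if (!all(c("x", "y", "z", "q", "site") %in% names(solute))) {
    ht_error("ht_config_error", "solute needs columns x, y, z, q, site")
  }
  structure(
    list(box_A = box_A, n_dipoles = as.integer(n_dipoles),
         dipole_charge_e = dipole_charge_e, dipole_sep_A = dipole_sep_A,
         reorient_sd = reorient_sd, polarization = polarization,
         solute = solute, seed = seed),
    class = "snapshot_config"
  )
}

# Toy stand-in solute: a charged single-guanine probe site and a neutral
# triple-guanine stack, each represented by a handful of point charges.
default_toy_solute <- function(box_A) {
  c0 <- box_A / 2
  g3 <- data.frame(
    x = c0 + c(-3.5, -4.3, -2.9), y = c0 + c(0, 0.8, -0.8), z = c0,
    q = c(0.5, 0.3, 0.2), site = "G3prime"
  )
  ggg <- data.frame(
    x = c0 + 3.5 + rep(c(-0.7, 0, 0.7), 3),
    y = c0 + rep(c(-0.9, 0, 0.9), each = 3),
    z = c0 + rep(c(-3.4, 0, 3.4), 3)[order(rep(1:3, 3))],
    q = rep(c(-0.1, 0.2, -0.1), 3), site = "GGG"
  )
  rbind(g3, ggg)
}

#' Synthetic point-charge snapshot trajectory
#'
#' Generates `n_frames` frames of the toy solvated system described by a
#' [snapshot_config()]: solute charges are fixed; each dipole keeps its
#' center but its orientation unit vector performs a Gaussian random walk
#' on the sphere (kick SD `reorient_sd` per frame, renormalized), relaxed
#' each frame toward the solvating orientation (negative end facing the
#' solute's positive charge centroid) with strength `polarization`. The
#' output is writable with [write_pqr()] and carries the site map of the
#' solute's `site` labels. Deterministic for a given `(config, seed)`.
#'
#' @param config A [snapshot_config()].
#' @param n_frames Number of frames (>= 1).
#' @return List of [charge_snapshot()] frames.
#' @export
generate_snapshot_series <- function(config, n_frames) {
  if (!inherits(config, "snapshot_config")) {
    ht_error("ht_invalid_parameter", "`config` must come from snapshot_config()")
  }
  stopifnot_scalar_number(n_frames, "n_frames", positive = TRUE)
  n_frames <- as.integer(n_frames)
  sol <- config$solute
  n_sol <- nrow(sol)
  nd <- config$n_dipoles
  sites <- split(seq_len(n_sol), sol$site)

  # dipole vector points from the -q to the +q charge; the solvating
  # orientation therefore points away from the solute's positive centroid
  pos_q <- sol$q > 0
  p_plus <- if (any(pos_q)) {
    colSums(sol[pos_q, c("x", "y", "z")] * sol$q[pos_q]) / sum(sol$q[pos_q])
  } else c(mean(sol$x), mean(sol$y), mean(sol$z))

  with_preserved_seed(config$seed, {
    centers <- matrix(runif(3 * nd, 0.05 * config$box_A, 0.95 * config$box_A),
                      ncol = 3)
    v_solv <- sweep(centers, 2, as.numeric(p_plus))
    v_solv <- v_solv / sqrt(rowSums(v_solv^2))
    orient <- matrix(rnorm(3 * nd), ncol = 3)
    orient <- orient / sqrt(rowSums(orient^2))

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (nd > 0L && (config$reorient_sd > 0 || config$polarization > 0)) {
        orient <- (1 - config$polarization) * orient +
          config$polarization * v_solv +
          matrix(rnorm(3 * nd, 0, config$reorient_sd), ncol = 3)
        orient <- orient / sqrt(rowSums(orient^2))
      }
      if (nd > 0L) {
        half <- (config$dipole_sep_A / 2) * orient
        pos <- rbind(as.matrix(sol[, c("x", "y", "z")]),
                     centers + half, centers - half)
        q <- c(sol$q, rep(config$dipole_charge_e, nd),
               rep(-config$dipole_charge_e, nd))
        nm <- c(rep("S", n_sol), rep(c("DP", "DM"), each = nd))
        rid <- c(seq_len(n_sol), rep(n_sol + seq_len(nd), 2))
        rnm <- c(rep("SOL", n_sol), rep("WAT", 2 * nd))
      } else {
        pos <- as.matrix(sol[, c("x", "y", "z")])
        q <- sol$q
        nm <- rep("S", n_sol); rid <- seq_len(n_sol)
        rnm <- rep("SOL", n_sol)
      }
      frames[[f]] <- charge_snapshot(pos, q, sites = sites, model = f,
                                     atom_names = nm, res_names = rnm,
                                     res_ids = rid)
    }
    frames
  })
}
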