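test_that("OU noise has the exact stationary moments", {
  expect_identical(ou_process(100, 0.5, 0, 10, seed = 1), numeric(100))

  n <- 2e5
  x <- ou_process(n, 0.5, 0.15, 10, seed = 123)
  # variance: SE of the sample SD of a correlated series; use the effective
  # sample size n * dt / (2 tau_c)
  n_eff <- n * 0.5 / (2 * 10)
  se_sd <- 0.15 / sqrt(2 * n_eff)
  expect_lt(abs(sd(x) - 0.15), 3 * se_sd)

  rho1 <- cor(x[-1], x[-n])
  se_rho <- (1 - exp(-0.5 / 10)^2) / sqrt(n_eff)
  expect_lt(abs(rho1 - exp(-0.5 / 10)), 3 * se_rho)

  # determinism and stream independence
  expect_identical(x, ou_process(n, 0.5, 0.15, 10, seed = 123))
  expect_false(identical(x[1:10], ou_process(10, 0.5, 0.15, 10, seed = 124)))
})

test_that("noiseless gap traces cross zero exactly at the configured time", {
  cfg <- trace_config(sigma_eV = 0)
  tr <- generate_gap_trace(cfg, 1)
  g <- gap_trace(tr)
  expect_equal(g$gap_eV[1], -2)
  # crossing of the raw ramp at 800 ps, clamped at zero afterwards
  expect_equal(min(which(g$gap_eV >= 0)), which(tr$time_ps == 800))
  expect_true(all(g$gap_eV[tr$time_ps > 800] == 0))
  # the clamp flattens the approach to zero, so the smoothed crossing sits
  # half a window past the analytic 800 ps
  expect_equal(equalization_time(g)$t_eq_ps, 825, tolerance = 1e-6)
  # explicit slope configuration is equivalent
  cfg2 <- trace_config(sigma_eV = 0, slope_eV_ps = 2.5e-3)
  expect_equal(gap_trace(generate_gap_trace(cfg2, 1))$gap_eV, g$gap_eV)
})

test_that("replicates are deterministic and differ from one another", {
  cfg <- trace_config()
  a <- generate_gap_trace(cfg, 2)
  b <- generate_gap_trace(cfg, 2)
  expect_identical(a$e_donor, b$e_donor)
  expect_false(identical(generate_gap_trace(cfg, 1)$e_donor, a$e_donor))
  # replicate seeds are base + 0, 1, ...: replicate 2 under base seed s
  # equals replicate 1 under base seed s + 1
  cfg_shift <- trace_config(seed = cfg$seed + 1)
  expect_identical(generate_gap_trace(cfg_shift, 1)$e_donor, a$e_donor)
})

test_that("the default emulation recovers its equalization time end-to-end", {
  cfg <- trace_config()
  reps <- lapply(1:3, function(r) generate_gap_trace(cfg, r))
  gap <- gap_trace(replicate_average(reps))
  eq <- equalization_time(gap)
  expect_true(eq$found)
  expect_lt(abs(eq$t_eq_ps - 800), 80)
})

test_that("gap noise has the configured amplitude and common mode cancels", {
  cfg <- trace_config(slope_eV_ps = 0, gap0_eV = 0, duration_ps = 5e4)
  g <- gap_trace(generate_gap_trace(cfg, 1))$gap_eV
  n_eff <- length(g) * 0.5 / (2 * 10)
  expect_lt(abs(sd(g) - 0.15), 3 * 0.15 / sqrt(2 * n_eff))

  cfg_cm <- trace_config(slope_eV_ps = 0, gap0_eV = 0, duration_ps = 1000,
                         common_mode_sigma_eV = 0.5)
  cfg_no <- trace_config(slope_eV_ps = 0, gap0_eV = 0, duration_ps = 1000)
  expect_equal(gap_trace(generate_gap_trace(cfg_cm, 1))$gap_eV,
               gap_trace(generate_gap_trace(cfg_no, 1))$gap_eV,
               tolerance = 1e-12)
})

test_that("potential signals carry the planted harmonics", {
  # a 740 cm^-1 mode has a ~45 fs period: first maximum of the noiseless
  # cosine at ~45 fs
  cfg <- trace_config(duration_ps = 1, dt_ps = 1e-3, sigma_eV = 0,
                      harmonics = data.frame(wavenumber_cm1 = 740,
                                             amplitude = 1, phase = 0))
  sig <- generate_potential_signal(cfg)
  x <- sig$potential_V
  t_fs <- sig$time_ps * 1000
  interior_max <- which(diff(sign(diff(x))) == -2) + 1
  expect_lt(abs(t_fs[interior_max[1]] - 45), 1.5)

  cfg3 <- trace_config(duration_ps = 10, dt_ps = 1e-3, sigma_eV = 0.05,
                       tau_c_ps = 0.05, level = -10,
                       harmonics = data.frame(
                         wavenumber_cm1 = c(300, 1500, 2900),
                         amplitude = 0.5))
  sp <- fourier_spectrum(generate_potential_signal(cfg3, seed = 5))
  bin <- sp$wavenumber_cm1[2] - sp$wavenumber_cm1[1]
  for (w in c(300, 1500, 2900)) {
    sel <- abs(sp$wavenumber_cm1 - w) <= bin
    expect_gt(max(sp$power[sel]), 10 * stats::median(sp$power))
  }

  flat <- generate_potential_signal(trace_config(duration_ps = 1,
                                                 dt_ps = 1e-3, sigma_eV = 0,
                                                 level = -8))
  expect_true(all(flat$potential_V == -8))

  expect_error(
    generate_potential_signal(trace_config(
      duration_ps = 10, dt_ps = 0.5, sigma_eV = 0,
      harmonics = data.frame(wavenumber_cm1 = 740, amplitude = 1))),
    class = "ht_config_error")
})

test_that("snapshot series respect charge structure and determinism", {
  cfg0 <- snapshot_config(n_dipoles = 0)
  frames0 <- generate_snapshot_series(cfg0, 4)
  tr0 <- potential_trace(frames0, "G3prime")
  expect_equal(length(unique(tr0$potential_V)), 1L)  # frozen solute only

  cfg <- snapshot_config(n_dipoles = 30)
  frames <- generate_snapshot_series(cfg, 6)
  # every water-like dipole is exactly neutral; frame total equals solute
  expect_equal(frames[[3]]$total_charge, sum(cfg$solute$q), tolerance = 1e-12)

  # doubling the dipole charge doubles the dipole contribution
  cfg2 <- snapshot_config(n_dipoles = 30, dipole_charge_e = 2 * 0.417)
  frames2 <- generate_snapshot_series(cfg2, 6)
  p <- site_midpoint(frames[[5]], "GGG")
  v1 <- coulomb_potential(frames[[5]], p, exclude_site = "GGG")
  v2 <- coulomb_potential(frames2[[5]], p, exclude_site = "GGG")
  v_sol_excl <- coulomb_potential(frames0[[1]], p, exclude_site = "GGG")
  expect_equal(v2 - v_sol_excl, 2 * (v1 - v_sol_excl), tolerance = 1e-9)
})

test_that("generated snapshots round-trip through PQR at format precision", {
  frames <- generate_snapshot_series(snapshot_config(n_dipoles = 10), 3)
  path <- tempfile(fileext = ".pqr")
  write_pqr(frames, path)
  back <- read_pqr(path, sites = frames[[1]]$sites)
  expect_length(back, 3)
  for (m in 1:3) {
    expect_lt(max(abs(back[[m]]$coords - frames[[m]]$coords)), 1e-3)
    expect_lt(max(abs(back[[m]]$charges - frames[[m]]$charges)), 1e-3)
  }
  expect_identical(back[[2]]$sites, frames[[2]]$sites)
})
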