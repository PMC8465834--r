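make_trace <- function(n = 100, dt = 0.5, f = function(t) sin(t / 5)) {
  t <- seq(0, by = dt, length.out = n)
  site_energy_trace(t, value = f(t))
}

test_that("gap traces difference the channels with the hole-picture sign", {
  t <- seq(0, 99.5, 0.5)
  tr <- site_energy_trace(t, e_donor = rep(-7, length(t)),
                          e_acceptor = rep(-5, length(t)))
  g <- gap_trace(tr)
  expect_equal(unique(g$gap_eV), -2)    # donor 2 eV below the acceptor
  same <- site_energy_trace(t, e_donor = sin(t), e_acceptor = sin(t))
  expect_equal(gap_trace(same)$gap_eV, rep(0, length(t)))
  # linearity under channel scaling
  a <- 3.7
  scaled <- site_energy_trace(t, e_donor = a * sin(t), e_acceptor = a * cos(t))
  expect_equal(gap_trace(scaled)$gap_eV, a * (sin(t) - cos(t)))
  expect_error(gap_trace(make_trace()), class = "ht_missing_channel")
})

test_that("trace construction validates the grid", {
  expect_error(site_energy_trace(c(0, 1, 1.5), value = 1:3),
               class = "ht_grid_error")
  expect_error(site_energy_trace(c(0, 2, 1), value = 1:3),
               class = "ht_grid_error")
  expect_error(site_energy_trace(0.5, value = 1),
               class = "ht_invalid_parameter")
  expect_error(site_energy_trace(c(0, 1), e_donor = c(1, 2)),
               class = "ht_missing_channel")
})

test_that("replicate averaging is a pointwise mean with SEM", {
  t <- seq(0, 49.5, 0.5)
  up <- site_energy_trace(t, value = rep(1, length(t)))
  dn <- site_energy_trace(t, value = rep(-1, length(t)))
  avg <- replicate_average(list(up, dn))
  expect_equal(avg$value, rep(0, length(t)))
  expect_equal(avg$sem$value, rep(1, length(t)))  # SD sqrt(2), /sqrt(2)

  single <- replicate_average(list(up))
  expect_equal(single$value, up$value)
  expect_true(all(is.na(single$sem$value)))

  shifted <- site_energy_trace(t + 0.25, value = rep(1, length(t)))
  expect_error(replicate_average(list(up, shifted)),
               class = "ht_alignment_error")
})

test_that("replicate averaging recovers an OU ensemble mean within 3 SEM", {
  n <- 800; dt <- 0.5
  t <- seq(0, by = dt, length.out = n)
  truth <- -1 + 0.002 * t
  reps <- lapply(1:30, function(r) {
    site_energy_trace(t, value = truth + ou_process(n, dt, 0.15, 10,
                                                    seed = 300 + r))
  })
  avg <- replicate_average(reps)
  miss <- abs(avg$value - truth) > 3 * avg$sem$value
  # the estimated SEM puts ~0.6% of points beyond 3 SEM at 29 df; allow
  # headroom for the serial correlation of the failure indicator
  expect_lt(mean(miss), 0.02)
})

test_that("averaging and gap extraction commute", {
  t <- seq(0, 199.5, 0.5)
  reps <- lapply(1:3, function(r) {
    set.seed(500 + r)
    site_energy_trace(t, e_donor = rnorm(length(t)),
                      e_acceptor = rnorm(length(t)))
  })
  a <- gap_trace(replicate_average(reps))
  b <- replicate_average(lapply(reps, gap_trace))
  expect_equal(a$gap_eV, b$gap_eV, tolerance = 1e-12)
})

test_that("the ACF estimator equals the brute-force oracle", {
  # alternating series: lag-1 value is -(N-1)/N under N-normalization
  alt <- site_energy_trace(seq(0, 3.5, 0.5), value = rep(c(1, -1), 4))
  a <- autocorrelation(alt, max_lag_ps = 1)
  expect_identical(a$acf[1], 1)
  expect_equal(a$acf[2], -7 / 8)

  set.seed(77)
  for (n in c(64, 257, 1000)) {
    x <- rnorm(n)
    tr <- site_energy_trace(seq(0, by = 0.5, length.out = n), value = x)
    lmax_ps <- 0.5 * floor(n / 3)
    a <- autocorrelation(tr, max_lag_ps = lmax_ps)
    expect_equal(a$acf, brute_force_acf(x, floor(n / 3)), tolerance = 1e-12)
  }
})

test_that("the ACF is invariant under affine transforms of the signal", {
  set.seed(9)
  x <- cumsum(rnorm(300))
  t <- seq(0, by = 0.5, length.out = 300)
  a0 <- autocorrelation(site_energy_trace(t, value = x))
  a1 <- autocorrelation(site_energy_trace(t, value = -2.5 * x + 7))
  expect_equal(a0$acf, a1$acf, tolerance = 1e-10)
})

test_that("zero-variance series are rejected as degenerate", {
  flat <- site_energy_trace(seq(0, 49.5, 0.5), value = rep(3, 100))
  expect_error(autocorrelation(flat), class = "ht_degenerate_input")
})

test_that("the ACF half-period doubles the first reversal lag", {
  # cosine ACF: cos(pi * tau / 900) turns negative at 450 ps
  t <- seq(0, 5999.5, 0.5)
  tr <- site_energy_trace(t, value = cos(pi * t / 900))
  a <- autocorrelation(tr, max_lag_ps = 1500)
  hp <- acf_half_period(a, window_ps = 0)
  expect_true(hp$found)
  expect_equal(hp$reversal_lag_ps, 450, tolerance = 1e-2)
  expect_equal(hp$half_period_ps, 900, tolerance = 1e-2)
  # the extremum reading doubles the cosine's minimum lag instead
  hpe <- acf_half_period(a, window_ps = 0, method = "extremum")
  expect_equal(hpe$reversal_lag_ps, 900, tolerance = 2)

  # a monotone exponential decay has no reversal
  dec <- site_energy_trace(t, value = exp(-t / 200) +
                             1e-3 * sin(t))   # tiny ripple, variance > 0
  amono <- autocorrelation(dec, max_lag_ps = 500)
  expect_false(acf_half_period(amono, window_ps = 50)$found)
})

test_that("the synthetic emulation ACF reversal matches an exhaustive scan", {
  cfg <- trace_config()
  reps <- lapply(1:3, function(r) generate_gap_trace(cfg, r))
  gap <- gap_trace(replicate_average(reps))
  a <- autocorrelation(gap)
  hp <- acf_half_period(a, window_ps = 50)
  expect_true(hp$found)
  # oracle: smooth identically, scan for the first negative value
  k <- 2 * round(50 / (2 * 0.5)) + 1
  s <- as.numeric(stats::filter(a$acf, rep(1 / k, k), sides = 2))
  first_neg <- which(s < 0 & !is.na(s))[1]
  expect_lt(abs(hp$reversal_lag_ps - a$lag_ps[first_neg]), 0.5)
  expect_equal(hp$half_period_ps, 2 * hp$reversal_lag_ps)
})

test_that("equalization time finds the smoothed zero crossing", {
  t <- seq(0, 1999.5, 0.5)
  # unclamped ramp: a centered window preserves the analytic crossing
  ramp <- -2 + 2.5e-3 * t
  eq <- equalization_time(site_energy_trace(t, value = ramp))
  expect_true(eq$found)
  expect_equal(eq$t_eq_ps, 800, tolerance = 1e-6)

  const <- site_energy_trace(t, value = rep(-1, length(t)))
  eqc <- equalization_time(const)
  expect_false(eqc$found)
  expect_equal(eqc$final_smoothed_value, -1)

  # linear-fit mode intersects the pre-crossing fit with zero
  eqf <- equalization_time(site_energy_trace(t, value = ramp),
                           mode = "linear_fit")
  expect_equal(eqf$t_eq_ps, 800, tolerance = 1e-6)

  # clamping at zero flattens the approach: the smoothed trace first
  # touches zero half a window late, at 800 + 25 ps
  clamped <- equalization_time(site_energy_trace(t, value = pmin(0, ramp)))
  expect_equal(clamped$t_eq_ps, 825, tolerance = 1e-6)
})

test_that("equalization survives OU noise within +/- 80 ps", {
  t <- seq(0, 1999.5, 0.5)
  ramp <- pmin(0, -2 + 2.5e-3 * t)
  noisy <- site_energy_trace(t, value = ramp + ou_process(length(t), 0.5,
                                                          0.15, 10, seed = 8))
  eq <- equalization_time(noisy)
  expect_lt(abs(eq$t_eq_ps - 800), 80)
})

test_that("equalization is shift-equivariant and scale-invariant", {
  t <- seq(0, 1999.5, 0.5)
  x <- pmin(0, -2 + 2.5e-3 * t) + ou_process(length(t), 0.5, 0.1, 10,
                                             seed = 31)
  base <- equalization_time(site_energy_trace(t, value = x))$t_eq_ps
  shifted <- equalization_time(site_energy_trace(t + 250, value = x))$t_eq_ps
  expect_equal(shifted - base, 250, tolerance = 1e-9)
  scaled <- equalization_time(site_energy_trace(t, value = 4 * x))$t_eq_ps
  expect_equal(scaled, base, tolerance = 1e-9)
})
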