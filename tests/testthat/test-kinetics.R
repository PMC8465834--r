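test_that("Arrhenius activation follows the uphill-only exponential law", {
  # zero barrier returns the prefactor exactly
  expect_identical(arrhenius_activation(1e10, 0, 300), 1e10)
  # barrier of exactly kB*T attenuates by 1/e
  kBT <- ht_constants$kB_eV * 300
  expect_equal(arrhenius_activation(1e10, kBT, 300), 1e10 / exp(1))
  # independently evaluated scalar: exp(-0.05953/0.0258520) = 0.1000
  expect_rel_equal(arrhenius_activation(2e10, 0.05953, 300), 2e9, 1e-3)
  # downhill is capped at the prefactor (resonance-seeking cannot beat the
  # solvent-limited rate)
  expect_identical(arrhenius_activation(1e10, -0.5, 300), 1e10)
  expect_true(all(vapply(seq(0, 1, 0.1), function(dE)
    arrhenius_activation(1e10, dE, 300) <= 1e10, logical(1))))
  # an infinite barrier closes the channel exactly
  expect_identical(arrhenius_activation(1e10, Inf, 300), 0)
  expect_error(arrhenius_activation(1e10, 0.1, -5), class = "ht_error")
})

test_that("the scheme generator has the mechanism's arrow structure", {
  sc <- build_scheme(rate_set(k_act0 = 1e10, dE_DA = 0.05, dE_AD = 0.3,
                              k_HT = 1e12))
  Q <- sc$Q
  # exactly 8 arrows: activation (2), tunneling (2), relaxation (2),
  # damage (2)
  off <- Q; diag(off) <- 0
  expect_identical(sum(off > 0), 8L)
  # generator property: columns sum to zero (probability conservation)
  expect_equal(max(abs(colSums(Q))), 0)
  # absorbing products have no outflow
  expect_identical(unname(Q[, "PD"]), rep(0, 6))
  expect_identical(unname(Q[, "PA"]), rep(0, 6))
  # tunneling is symmetric
  expect_identical(Q["Astar", "Dstar"], Q["Dstar", "Astar"])
  # all rates zero -> zero matrix (every state de facto absorbing)
  sc0 <- build_scheme(rate_set(k_act0 = 0, k_rel_D = 0, k_rel_A = 0,
                               k_HT = 0, k_dam_D = 0, k_dam_A = 0))
  expect_identical(unname(sc0$Q), matrix(0, 6, 6))
})

test_that("absorption solver matches the closed-form reverse-free ratio", {
  # no tunneling: no path to the acceptor, all damage at the donor
  y0 <- solve_yields_absorption(build_scheme(reverse_free_rates(k_HT = 0)))
  expect_equal(y0$p_PD, 1)
  expect_identical(y0$ratio, 0)
  expect_true(y0$degenerate)

  # the two calibration points of the printed table
  for (kht in c(6.01e12, 2.51e10)) {
    y <- solve_yields_absorption(build_scheme(reverse_free_rates(k_HT = kht)))
    expect_rel_equal(y$ratio, closed_form_ratio(1e10, 1e7, 1e13, kht), 1e-10)
    expect_equal(y$p_PD + y$p_PA, 1, tolerance = 1e-12)
  }
  expect_rel_equal(
    solve_yields_absorption(build_scheme(reverse_free_rates(k_HT = 6.01e12)))$ratio,
    273, 5e-3)
  expect_rel_equal(
    solve_yields_absorption(build_scheme(reverse_free_rates(k_HT = 2.51e10)))$ratio,
    2.5, 5e-3)
})

test_that("only one absorbing channel reachable gives a pure yield", {
  rs <- rate_set(k_act0 = 1e10, dE_DA = 0, dE_AD = 0.3, k_HT = 1e12,
                 k_dam_D = 0, k_dam_A = 3e6)
  y <- solve_yields_absorption(build_scheme(rs))
  expect_equal(y$p_PA, 1, tolerance = 1e-12)
  expect_identical(y$ratio, Inf)
  expect_true(y$degenerate)
})

test_that("ODE propagation agrees with the absorption solve and conserves mass", {
  sc <- build_scheme(reverse_free_rates(k_HT = 6.01e12))
  ya <- solve_yields_absorption(sc)
  yo <- solve_yields_ode(sc)
  expect_rel_equal(yo$ratio, ya$ratio, 1e-8)
  expect_lt(yo$diagnostics$residual, 1e-12)
  # probability conservation at every reported time
  traj <- yo$diagnostics$trajectory
  totals <- rowSums(traj[, -1])
  expect_lt(max(abs(totals - 1)), 1e-9)
})

test_that("ODE and absorption routes agree on randomized wide-spread schemes", {
  set.seed(421)
  for (i in 1:25) {
    sc <- build_scheme(random_rate_set_wide())
    ya <- solve_yields_absorption(sc)
    yo <- solve_yields_ode(sc, transient_tol = 1e-15)
    expect_rel_equal(yo$ratio, ya$ratio, 1e-6)
  }
})

test_that("yield ratio is linear in the activation rate without reverse flow", {
  base <- vapply(c(1e8, 1e9, 1e10, 1e11), function(k_act) {
    sc <- build_scheme(reverse_free_rates(k_act0 = k_act, k_HT = 1e12))
    solve_yields_absorption(sc)$ratio / k_act
  }, numeric(1))
  expect_lt(max(abs(base / base[1] - 1)), 1e-9)
})

test_that("yield ratio is monotone in k_HT, k_act and k_dam_D", {
  r_of <- function(k_act0 = 1e10, k_HT = 1e11, k_dam_D = 1e7) {
    solve_yields_absorption(build_scheme(
      reverse_free_rates(k_act0 = k_act0, k_HT = k_HT, k_dam_D = k_dam_D)
    ))$ratio
  }
  grid <- 10^seq(9, 13, 0.5)
  expect_true(all(diff(vapply(grid, function(k) r_of(k_HT = k),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(10^seq(8, 11, 0.5), function(k)
    r_of(k_act0 = k), numeric(1))) > 0))
  expect_true(all(diff(vapply(10^seq(6, 9, 0.5), function(k)
    r_of(k_dam_D = k), numeric(1))) < 0))
})

test_that("degenerate and invalid kinetic inputs raise typed errors", {
  expect_error(rate_set(k_act0 = -1), class = "ht_invalid_parameter")
  expect_error(rate_set(temperature = 0), class = "ht_invalid_parameter")
  sc <- build_scheme(reverse_free_rates(k_HT = 1e12))
  expect_error(solve_yields_absorption(sc, initial = "PD"),
               class = "ht_invalid_parameter")
  expect_error(solve_yields_absorption(sc, initial = "X"),
               class = "ht_invalid_parameter")
  # a reachable transient state with zero outflow traps mass: A is fed by
  # relaxation but has no damage channel and no reverse activation
  rs <- rate_set(k_act0 = 1e10, dE_DA = 0, dE_AD = Inf, k_HT = 1e12,
                 k_rel_A = 1e13, k_dam_A = 0, k_dam_D = 1e7)
  expect_error(solve_yields_absorption(build_scheme(rs)),
               class = "ht_structural_error")
})

test_that("Gillespie simulation is reproducible and finds the closed channels", {
  sc0 <- build_scheme(reverse_free_rates(k_HT = 0))
  y <- stochastic_yields(sc0, 500, seed = 11)
  expect_identical(y$p_PD, 1)           # no path to the acceptor
  sc <- build_scheme(reverse_free_rates(k_act0 = 1e9, k_HT = 1e12))
  y1 <- stochastic_yields(sc, 3000, seed = 42)
  y2 <- stochastic_yields(sc, 3000, seed = 42)
  expect_identical(y1$p_PA, y2$p_PA)    # same seed, same result
  y3 <- stochastic_yields(sc, 3000, seed = 43)
  expect_false(identical(y1$p_PA, y3$p_PA))
  expect_identical(y1$diagnostics$n_capped, 0)
})

test_that("Gillespie yields sit within 3 binomial SE of the exact solve", {
  set.seed(1305)
  for (i in 1:3) {
    sc <- build_scheme(random_rate_set_physical())
    exact <- solve_yields_absorption(sc)
    y <- stochastic_yields(sc, 2e4, seed = 100 + i)
    se <- sqrt(exact$p_PA * (1 - exact$p_PA) / 2e4)
    expect_lt(abs(y$p_PA - exact$p_PA), 3 * se + 1e-12)
  }
})
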