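# holetransfer

Kinetics and trajectory diagnostics of hole transfer in oxidized DNA.

When DNA is oxidized, the resulting positive charge (hole) migrates between
guanine sites and ends as oxidative damage, preferentially at stacked-guanine
traps (GG, GGG). The rate-limiting step of guanine-to-guanine transfer is the
*solvent*: water and counterions must bring the donor and acceptor hole
levels into vibronic resonance before the hole can tunnel. `holetransfer` is
an R package for the two computations that quantify this picture:

* **Kinetic modeling.** A six-state absorbing master equation over
  `{D, D*, A*, A, PD, PA}` with four elementary steps — Arrhenius-activated
  resonance `k_act = k_act0 · exp(−max(0, ΔE)/kB·T)`, symmetric coherent
  tunneling `k_HT` between the resonant ensembles, solvent relaxation
  `k_rel = 1e13 s⁻¹`, and damage (radical-cation deprotonation)
  `k_dam = 1e7 / 3e6 s⁻¹` for G / stacked G. Terminal damage-yield
  probabilities `p(PD)`, `p(PA)` come from an exact absorption solve, stiff
  matrix-exponential propagation, or compiled Gillespie sampling;
  `calibrate_kht()` recovers the tunneling rate from an observed yield ratio
  and `predict_table1()` transfers a calibrated yield-ratio table from one
  activation time `τ_act = 1/k_act` to another.
* **Trajectory statistics.** Estimators applied to MD/QM-MM-style time
  series: donor−acceptor gap traces `ΔE(t)` and replicate averages, the
  N-normalized gap autocorrelation `ACF(ℓ) = ⟨δE(0)δE(ℓ)⟩/⟨(δE)²⟩` and its
  reversal half-period, the level-equalization time (smoothed zero
  crossing), Coulomb site potentials `V = ke·Σ qᵢ/rᵢ` at nucleobase-site
  midpoints over multi-model PQR snapshots, and Hann-windowed power spectra
  on a wavenumber axis.
* **Synthetic data.** Generators for gap trajectories (linear ramp from
  −2 eV clamped at zero, exact-discretization Ornstein–Uhlenbeck noise),
  fs-sampled potential-like signals with planted 100–3000 cm⁻¹ harmonics,
  and toy solvated point-charge snapshot series — so the full pipeline runs
  and is tested without any simulation software.

## Worked example

Calibrate the tunneling rate so the two-site scheme (reverse activation
closed, `k_act = 1e10 s⁻¹`, i.e. `τ_act = 100 ps`) reproduces a yield ratio
of 273, then predict the whole ratio column at `τ_act = 900 ps`:

```r
library(holetransfer)

rs <- rate_set(k_act0 = 1e10, dE_DA = 0, dE_AD = Inf)  # reverse-free
k  <- calibrate_kht(273, rs)
k
#> 6.013216e+12
rs$k_HT <- k
solve_yields_absorption(build_scheme(rs))
#> Oxidative-damage yields (absorption method):
#>   p(PD) = 0.00364964   p(PA) = 0.99635   PA/PD ratio = 273

predict_table1(900, 100, c(273, 42, 5.2, 3.0, 2.5, 2.2, 2.0))
#>   n predicted_ratio calibration_ratio     k_HT
#> 1 1          30.333             273.0 6.01e+12
#> 2 2           4.667              42.0 4.59e+11
#> 3 3           0.578               5.2 5.25e+10
#> 4 4           0.333               3.0 3.02e+10
#> 5 5           0.278               2.5 2.51e+10
#> 6 6           0.244               2.2 2.21e+10
#> 7 7           0.222               2.0 2.01e+10
```

Slowing activation ninefold divides every ratio by nine (the reverse-free
ratio is linear in `k_act`): damage shifts away from the distal GGG trap
toward the injection G. The calibrated `k_HT` column decays steeply with
bridge length `n`, as expected for tunneling across a growing (T)n bridge.

The simulate-then-analyze pipeline generates three replicate gap
trajectories (2 ns, 0.5 ps sampling, equalization configured at 800 ps),
averages them, and estimates the solvent activation time two ways:

```r
run_pipeline(list(pipeline = "trace", seed = 1))
#> $t_eq_ps                  764.1      # smoothed zero crossing of ΔE(t)
#> $half_period_ps           1143       # 2 × first ACF sign reversal
#> $kact_from_t_eq_s1        1.31e9     # k_act = 1/τ
#> $kact_from_half_period_s1 8.75e8
```

Both estimates sit near the configured ~1e9 s⁻¹ activation rate, an order
of magnitude below the 1e10 s⁻¹ regime that reproduces fast-activation
yield columns — the quantitative tension the kinetic model lets you
explore.

A thin command-line front end over the same functions lives at
`inst/cli/holetransfer.R` (subcommands `simulate-trace`, `acf`,
`equalization`, `spectrum`, `potential`, `yields`, `calibrate`, `table1`,
`run`).

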