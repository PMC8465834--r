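---
title: "Modeling solvent-gated hole transfer in oxidized DNA"
author: "holetransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling solvent-gated hole transfer in oxidized DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holetransfer)
```

## The scientific problem

When double-stranded DNA loses an electron, the resulting positive charge
(a *hole*) migrates between guanine sites, where it eventually triggers
oxidative damage. Guanine is the most easily oxidized natural nucleobase,
and stacked runs of guanines (GG, GGG) form still deeper hole traps. The
key bottleneck in hole transfer between a single G and a GGG stack is not
the electron tunneling itself but the *solvent response*: water and
counterions must rearrange until the donor and acceptor hole levels are
degenerate (vibronic resonance), and only then can the hole tunnel
coherently. This package implements two linked pipelines around that
picture:

1. a **four-step kinetic model** of hole transport with absorbing
   damage products, used to connect the resonance-activation time to
   observable damage-yield ratios; and
2. **trajectory statistics** that estimate the activation time from
   site-energy time series of the kind produced by MD simulations with
   QM/MM single points: gap traces, replicate averages, autocorrelation,
   equalization time, Coulomb site potentials, and Fourier spectra.

A synthetic-data module generates trajectories with the statistical
structure the estimators assume, so the full pipeline is testable without
any molecular-simulation software.

## The kinetic model

Six states describe one donor/acceptor pair: `D` (hole on the donor),
`D*` and `A*` (solvent-activated resonant ensembles), `A` (hole relaxed
on the acceptor), and the absorbing damage products `PD` and `PA`. The
arrows are

* activation `D -> D*` and `A -> A*` at the Arrhenius rate
  $k_{act} = k_{act}^0(T)\,e^{-\max(0,\Delta E)/k_B T}$,
* coherent tunneling `D* <-> A*` at $k_{HT}$ (symmetric in resonance),
* solvent relaxation `D* -> D`, `A* -> A` at $k_{rel}$, and
* damage `D -> PD`, `A -> PA` at $k_{dam}$ (radical-cation
  deprotonation).

Defaults fix $k_{rel} = 10^{13}\,\mathrm{s^{-1}}$ (solvent relaxation is
a tens-of-femtoseconds process), $k_{dam} = 10^{7}$ and
$3\times10^{6}\,\mathrm{s^{-1}}$ for G and stacked-G radical cations,
and $T = 300$ K with $k_B = 8.617333262\times10^{-5}$ eV/K.

### Design choices in the model

**Uphill-only activation.** A literal reading of the Arrhenius
expression with a negative $\Delta E$ would make activation faster than
its own prefactor, which is unphysical: resonance-seeking is limited by
the solvent. We therefore clamp the exponent at zero
(`max(0, dE)`), and the forward and reverse site-energy differences are
supplied separately (`dE_DA`, `dE_AD`). Setting `dE = Inf` closes a
channel exactly; the default reverse barrier of 0.3 eV (a deep GGG trap)
makes reverse activation negligible at 300 K without closing it.

**Two-site reduction.** Intervening bridge bases are not represented as
explicit states; bridge length enters only through $k_{HT}$, which is
calibrated per bridge length from an observed yield ratio. No per-state
bridge parameters are available to do better, and the calibration
absorbs whatever structure the bridge adds.

**Three solution routes, one contract.** Terminal yields are computed
by (i) an exact absorption linear solve on the transient block of the
generator (`solve_yields_absorption()`, the default — immune to the
seven-decade stiffness of the rate spread), (ii) time propagation with
the matrix exponential on a doubling time grid
(`solve_yields_ode()` — every reported population vector is
$e^{Qt}p_0$ computed directly, so conservation holds to machine
precision), and (iii) a compiled Gillespie jump-chain sampler
(`stochastic_yields()`). The three agree within their stated tolerances
in the test suite; the closed form
$\mathrm{ratio} = (k_{act}/k_{dam,D})\,k_{HT}/(2k_{HT}+k_{rel})$
for the reverse-free scheme is used as an independent oracle.

**Degenerate schemes.** States unreachable from the injection state are
removed before the linear solve, so an unreachable damage channel yields
exactly zero and the ratio is reported as `0` or `Inf` with a
`degenerate` flag rather than as an error. A *reachable* transient state
with no outflow is a genuine structural defect and raises a typed error.

**Calibration.** The yield ratio is strictly increasing in $k_{HT}$ and
saturates at $(k_{act}/k_{dam,D})/2$ for the reverse-free scheme, so
`calibrate_kht()` bisects on $\log_{10} k_{HT}$ over
$[10^6, 10^{14}]\,\mathrm{s^{-1}}$; unattainable targets report the
supremum. `predict_table1()` then transfers a calibrated column of yield
ratios from one activation time to another; in the reverse-free scheme
the prediction is exactly linear in $k_{act}$, so slowing activation
from 100 ps to 900 ps divides every ratio by 9. This linear-scaling
prediction reproduces published slow-activation columns to within about
15%; the residual deviations reflect rounding and bridge structure
beyond the two-site reduction, and we deliberately do not add parameters
to chase them.

```{r table1}
predict_table1(900, 100, c(273, 42, 5.2, 3.0, 2.5, 2.2, 2.0))
```

### Monte-Carlo route and its randomization

The Gillespie sampler simulates the embedded jump chain only: terminal
absorption probabilities of a continuous-time Markov chain are
independent of waiting times, so sampling exponential dwell times would
add cost without changing any reported quantity. Cross-checks against
the exact solver randomize rates in a physically plausible
guanine-oxidation regime (activation $10^8$–$10^{10}$, damage
$10^6$–$10^8$, tunneling $10^{10}$–$10^{13}\,\mathrm{s^{-1}}$,
relaxation fixed at $10^{13}$): this keeps expected jump counts near
$2k_{act}/k_{dam}$ per walker, i.e. bounded, while still exercising
yield probabilities across several decades. The solver-agreement
property (ODE vs. absorption) instead draws every rate log-uniformly
over $[10^6, 10^{13}]\,\mathrm{s^{-1}}$, since neither exact route
cares about jump counts.

## Trajectory statistics

### Gap traces and replicate averaging

The observable is the donor-minus-acceptor site-energy gap
$\Delta E(t)$, proxied in QM/MM work by fragment HOMO energies. The
sign convention follows the hole picture: with the hole stabilized on
the donor, the donor level lies ~2 eV *below* the acceptor, so the gap
starts near $-2$ eV and rises toward zero as the solvent equalizes the
levels. Replicate trajectories are averaged pointwise on identical
grids (mismatched grids are an error — no silent interpolation), with
the standard error of the mean attached.

### Autocorrelation and the activation half-period

The gap fluctuation ACF,
$\mathrm{ACF}(\ell) = \langle\delta E(0)\,\delta E(\ell)\rangle /
\langle(\delta E)^2\rangle$ with $\delta E = \Delta E - \langle\Delta
E\rangle$, uses the N-normalized (biased) estimator: it is the standard
stable choice at long lags and guarantees $\mathrm{ACF}(0)=1$ exactly.
The lag grid starts at one sampling interval — nothing below the 0.5 ps
sampling is resolvable — and extends to half the record by default.

The activation time is read off the ACF's first reversal, doubled. Two
reversal definitions are supported because the informal description in
this literature is ambiguous: for a cosine-shaped ACF, "the ACF reverses
direction at $\tau_r$ with half-period $2\tau_r$" is arithmetically
consistent only if $\tau_r$ is the first *sign change* (the quarter
period); the first *slope* reversal of a cosine is the half period
itself. We therefore default to the sign-change reading
(`method = "sign"`), which reproduces the cosine identity exactly, and
provide `method = "extremum"` for heavily damped ACFs that reverse
slope without changing sign. The scan runs on a smoothed ACF (50 ps
centered moving average by default) and a monotone ACF reports
`found = FALSE` rather than erroring.

### Equalization time

`equalization_time()` reports the first upward zero crossing of the
50 ps centered moving average of the gap (linearly interpolated between
samples). The window suppresses the ±0.1–0.2 eV fluctuation scale while
easily resolving an ~800 ps drift; it is exposed as a parameter. A
`linear_fit` mode intersects a straight-line fit of the pre-crossing
segment with zero instead, for traces whose rise is nearly linear —
neither mode is privileged. Two estimator properties deserve note:

* For an *unclamped* linear ramp the centered window preserves the
  crossing exactly. If the gap clamps at zero after the crossing (as
  the synthetic generator does), the smoothed trace approaches zero
  with vanishing slope and first touches it half a window late — a
  known, bounded +25 ps bias at the default window.
* After the clamp the gap mean is exactly zero, so the first crossing
  acquires a diffusive first-passage component. Across base seeds the
  recovered time is typically within ±40 ps of the configured 800 ps,
  but a minority of seeds wait out a long negative noise excursion and
  land 100–150 ps late. This tail is inherent to the
  first-zero-crossing definition under these noise parameters, not an
  implementation artifact.

### Coulomb site potentials

The electrostatic environment of a nucleobase site is probed as the
bare Coulomb sum $V = k_e \sum_i q_i/r_i$
($k_e = 14.399645$ V·Å/e) evaluated at the site's unweighted
coordinate centroid, per snapshot. The probed site's own atoms are
excluded — the self-potential is unphysical for an environment probe —
and there are no periodic images, no reaction field, and by default no
cutoff: the probe is a diagnostic, not an energy model. A spherical
cutoff is available for experiments. Multi-model PQR files are read and
written through bio3d, with the PQR charge column in the occupancy
slot.

### Fourier spectra

`fourier_spectrum()` removes the mean (or a linear trend), applies a
Hann taper by default, and reports single-sided power on a wavenumber
axis (1 THz = 33.35641 cm⁻¹, with $c$ fixed at
$2.99792458\times10^{10}$ cm/s). Each result carries its Parseval pair
(time-domain vs. frequency-domain energy of the windowed, detrended
signal), which the tests require to agree to $10^{-6}$ relative.
Resolving the 100–3000 cm⁻¹ vibrational band requires fs-scale
sampling; 0.5 ps sampling caps the axis at ~33 cm⁻¹.

## What the synthetic generator emulates — and what it does not

`generate_gap_trace()` models the gap as a deterministic linear ramp
from $-2.0$ eV, clamped at zero after the crossing (the levels stay
degenerate thereafter), plus stationary OU noise. The defaults are the
study conditions the estimators target: 2 ns records at 0.5 ps
sampling, equalization at 800 ps, three replicates with seeds
base$+0,1,2$. The gap-fluctuation scale $\sigma = 0.15$ eV with
$\tau_c = 10$ ps was chosen once to match the visual scatter of
published HOMO-gap traces (no numeric SD is printed there); both knobs
are exposed. `sigma_eV` parameterizes the *gap* SD; each channel
receives independent OU noise at $\sigma/\sqrt2$, and an optional
common-mode term (shared by both channels, cancelling exactly in the
gap) models correlated solvent drift. The deterministic-ramp reading is
the simplest testable interpretation of an "almost linear" level rise;
a relaxing stochastic mean would be equally defensible but adds an
unidentifiable parameter.

OU noise uses the exact discretization
$x_{t+1} = x_t e^{-\Delta t/\tau_c} + \sigma\sqrt{1 - e^{-2\Delta
t/\tau_c}}\,\xi_t$ with $x_0 \sim N(0, \sigma^2)$, so stationary
moments hold at any step size.

`generate_snapshot_series()` builds a deliberately toy solvated system:
a fixed point-charge solute (a +1 e single-guanine stand-in and a
neutral triple-guanine stack) among neutral two-charge dipoles whose
orientations random-walk with a mean-reverting pull (strength
`polarization`, default 0.4) toward solvating the positive site. The
bias emulates the oriented hydration shell around a cation and gives
both probed sites the negative mean potential a stabilized hole
experiences. What this generator does *not* emulate: real water
structure, force-field energetics, DNA geometry, or the published
per-site potential magnitudes — those are trajectory-specific and only
their sign and band structure are meaningful here. Passing tests
therefore certify the estimators' statistical behavior, not agreement
with any particular MD trajectory.

## Numerical choices and problem sizes

* Absorption solve: dense LU on the ≤4-state transient block; exact to
  solver precision.
* Time propagation: `Matrix::expm` (scaling-and-squaring) on a doubling
  grid from $1/\max|Q_{ii}|$ until transient mass drops below
  $10^{-12}$ (configurable; solver-agreement tests use $10^{-15}$ so
  yields as small as $10^{-7}$ are compared meaningfully).
* Calibration: `uniroot` on $\log_{10}k_{HT}$, tolerance far below the
  $10^{-4}$ relative contract.
* Monte Carlo: $10^5$ walkers for 3-SE agreement checks; per-walker
  jump budget $10^7$ with capped walkers counted, reported, and
  excluded rather than silently mixed in.
* Test-suite problem sizes: records of $10^3$–$2\times10^5$ samples,
  ACF oracles to $N = 1000$, 100 random schemes for solver agreement,
  10 for Monte-Carlo agreement — sizes chosen so the entire suite
  exercises every contract in well under a minute.

## Known limitations

* The two-site reduction cannot reproduce residual 5–15% deviations of
  published slow-activation yield columns; these would require explicit
  bridge states or the original tunneling-rate inputs.
* The equalization estimator's first-passage tail (above) means a
  minority of noise realizations miss the ±80 ps recovery band.
* The Coulomb probe ignores periodicity and polarization; it matches
  the diagnostic use it was built for, not an Ewald-quality potential.
* The absolute activation prefactor is not identifiable from yield
  ratios alone — `calibrate_kht()` absorbs it — so only *ratios* of
  activation times are meaningful in `predict_table1()`.
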