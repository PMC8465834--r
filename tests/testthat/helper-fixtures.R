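# Shared fixtures and independent oracles.

# Reverse-free two-site scheme with barrierless forward activation: the
# regime of the printed yield-ratio table.
reverse_free_rates <- function(k_act0 = 1e10, k_HT = 0, k_dam_D = 1e7,
                               k_dam_A = 3e6, k_rel = 1e13) {
  rate_set(k_act0 = k_act0, dE_DA = 0, dE_AD = Inf,
           k_rel_D = k_rel, k_rel_A = k_rel, k_HT = k_HT,
           k_dam_D = k_dam_D, k_dam_A = k_dam_A)
}

# Independently derived closed-form yield ratio for the reverse-free scheme
# with equal relaxation rates (first-step analysis on the jump chain).
closed_form_ratio <- function(k_act, k_dam_D, k_rel, k_HT) {
  (k_act / k_dam_D) * k_HT / (2 * k_HT + k_rel)
}

# Brute-force O(N^2) oracle for the N-normalized autocorrelation estimator.
brute_force_acf <- function(x, lag_max) {
  n <- length(x)
  d <- x - mean(x)
  denom <- sum(d * d) / n
  vapply(0:lag_max, function(l) {
    s <- 0
    for (t in seq_len(n - l)) s <- s + d[t] * d[t + l]
    (s / n) / denom
  }, numeric(1))
}

# Random scheme with every rate drawn log-uniformly (for solver agreement).
random_rate_set_wide <- function() {
  lu <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  rate_set(k_act0 = lu(1e6, 1e13), dE_DA = 0, dE_AD = runif(1, 0, 0.3),
           k_rel_D = lu(1e6, 1e13), k_rel_A = lu(1e6, 1e13),
           k_HT = lu(1e6, 1e13),
           k_dam_D = lu(1e6, 1e13), k_dam_A = lu(1e6, 1e13))
}

# Random scheme in the physically plausible guanine-oxidation regime
# (bounded activation/damage ratio, so jump counts stay modest for the
# Monte-Carlo cross-check).
random_rate_set_physical <- function() {
  lu <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  rate_set(k_act0 = lu(1e8, 1e10), dE_DA = 0, dE_AD = runif(1, 0.1, 0.3),
           k_rel_D = 1e13, k_rel_A = 1e13, k_HT = lu(1e10, 1e13),
           k_dam_D = lu(1e7, 1e8), k_dam_A = lu(1e6, 1e8))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
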