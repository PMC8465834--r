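#' Site-energy (or site-potential) time series
#'
#' Container for a uniformly sampled trajectory observable: either the pair
#' of donor/acceptor hole-site energies (HOMO-energy proxies, eV) or a
#' single signal channel such as an electrostatic potential (V). The time
#' grid must be strictly increasing and uniform to within `1e-9` relative;
#' at least two samples are required.
#'
#' @param time_ps Time grid, ps.
#' @param e_donor,e_acceptor Donor/acceptor site energies, eV (two-channel
#'   form). Supply both or neither.
#' @param value Single signal channel (single-channel form).
#' @param replicate Optional replicate identifier.
#' @param channel Label for the single channel (default `"value"`).
#' @return An object of class `site_energy_trace`: a list with `time_ps`,
#'   `dt_ps`, the channel(s), `replicate`, and `channel` names.
#' @export
site_energy_trace <- function(time_ps, e_donor = NULL, e_acceptor = NULL,
                              value = NULL, replicate = NA,
                              channel = "value") {
  time_ps <- as.numeric(time_ps)
  n <- length(time_ps)
  if (n < 2L) ht_error("ht_invalid_parameter", "trace needs >= 2 samples")
  if (anyNA(time_ps)) ht_error("ht_invalid_parameter", "NA in time grid")
  d <- diff(time_ps)
  if (any(d <= 0)) {
    ht_error("ht_grid_error", "time grid must be strictly increasing")
  }
  dt <- mean(d)
  if (max(abs(d - dt)) > 1e-9 * max(abs(time_ps[n]), dt)) {
    ht_error("ht_grid_error", "time grid is not uniform (1e-9 relative)")
  }
  two <- !is.null(e_donor) || !is.null(e_acceptor)
  if (two && (is.null(e_donor) || is.null(e_acceptor))) {
    ht_error("ht_missing_channel",
             "supply both e_donor and e_acceptor, or a single `value`")
  }
  if (two && !is.null(value)) {
    ht_error("ht_invalid_parameter", "give channels or `value`, not both")
  }
  if (!two && is.null(value)) {
    ht_error("ht_missing_channel", "no signal channel supplied")
  }
  chans <- if (two) list(e_donor = as.numeric(e_donor),
                         e_acceptor = as.numeric(e_acceptor))
           else setNames(list(as.numeric(value)), channel)
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n) {
      ht_error("ht_invalid_parameter",
               sprintf("channel '%s' length %d != %d time points",
                       nm, length(chans[[nm]]), n))
    }
  }
  structure(
    c(list(time_ps = time_ps, dt_ps = dt, replicate = replicate,
           channels = names(chans)), chans),
    class = "site_energy_trace"
  )
}

is_two_channel <- function(trace) {
  all(c("e_donor", "e_acceptor") %in% trace$channels)
}

single_channel <- function(trace) {
  if (is_two_channel(trace)) {
    ht_error("ht_invalid_parameter",
             "operation needs a single-channel trace (use gap_trace() first)")
  }
  trace[[trace$channels[[1]]]]
}

#' @export
print.site_energy_trace <- function(x, ...) {
  cat(sprintf("site_energy_trace: %d samples, dt = %g ps, span %g ps\n",
              length(x$time_ps), x$dt_ps,
              x$time_ps[length(x$time_ps)] - x$time_ps[1]))
  cat("  channels:", paste(x$channels, collapse = ", "))
  if (!is.na(x$replicate)) cat("  (replicate", x$replicate, ")")
  cat("\n")
  invisible(x)
}

#' Donor-acceptor energy-gap trace
#'
#' Elementwise difference `dE(t) = e_donor(t) - e_acceptor(t)` in eV. The
#' sign convention follows the hole picture: while the hole is more stable
#' on the donor, the donor HOMO lies *below* the acceptor and the gap is
#' negative (about -2 eV at injection), rising toward zero as the solvent
#' equalizes the two levels.
#'
#' @param trace A two-channel [site_energy_trace()].
#' @return A single-channel `site_energy_trace` (channel `"gap_eV"`).
#' @export
gap_trace <- function(trace) {
  if (!inherits(trace, "site_energy_trace")) {
    ht_error("ht_invalid_parameter", "`trace` must be a site_energy_trace")
  }
  if (!is_two_channel(trace)) {
    ht_error("ht_missing_channel",
             "gap_trace needs both e_donor and e_acceptor channels")
  }
  site_energy_trace(trace$time_ps,
                    value = trace$e_donor - trace$e_acceptor,
                    replicate = trace$replicate, channel = "gap_eV")
}

#' Pointwise average over replicate traces
#'
#' Averages replicate trajectories sharing an identical time grid. Each
#' signal channel is replaced by its pointwise mean; the standard error of
#' the mean (sample SD / sqrt(n)) is attached as an auxiliary `sem` list.
#' Grids must match exactly (no silent interpolation). A single replicate is
#' returned unchanged with `sem` flagged as undefined (`NA`).
#'
#' @param traces A list of [site_energy_trace()] objects with identical
#'   time grids and channel sets.
#' @return A `site_energy_trace` (replicate `"mean"`) with an extra `sem`
#'   element: a named list of per-channel SEM vectors, and `n_replicates`.
#' @export
replicate_average <- function(traces) {
  if (inherits(traces, "site_energy_trace")) traces <- list(traces)
  if (!length(traces)) ht_error("ht_invalid_parameter", "empty replicate list")
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    if (length(tr$time_ps) != length(ref$time_ps) ||
        max(abs(tr$time_ps - ref$time_ps)) > 1e-9 * max(1, abs(ref$time_ps))) {
      ht_error("ht_alignment_error",
               "replicate time grids differ; no silent interpolation is done")
    }
    if (!identical(sort(tr$channels), sort(ref$channels))) {
      ht_error("ht_alignment_error", "replicate channel sets differ")
    }
  }
  nrep <- length(traces)
  means <- list(); sems <- list()
  for (ch in ref$channels) {
    mat <- vapply(traces, function(tr) tr[[ch]], numeric(length(ref$time_ps)))
    mat <- matrix(mat, nrow = length(ref$time_ps))
    means[[ch]] <- rowMeans(mat)
    sems[[ch]] <- if (nrep > 1) apply(mat, 1, sd) / sqrt(nrep)
                  else rep(NA_real_, length(ref$time_ps))
  }
  out <- if (is_two_channel(ref)) {
    site_energy_trace(ref$time_ps, e_donor = means$e_donor,
                      e_acceptor = means$e_acceptor, replicate = "mean")
  } else {
    site_energy_trace(ref$time_ps, value = means[[ref$channels[[1]]]],
                      replicate = "mean", channel = ref$channels[[1]])
  }
  out$sem <- sems
  out$n_replicates <- nrep
  out
}
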