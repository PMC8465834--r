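#' Read a site-energy trace from TSV
#'
#' Reads a tab-separated trace file with a header line. Two layouts are
#' accepted: `time_ps`, `e_donor_eV`, `e_acceptor_eV` (optionally plus a
#' `replicate` column) for two-channel site-energy traces, or `time_ps`
#' plus one arbitrarily named value column for single-channel signals.
#' Cells must be numeric and the time grid uniform and increasing; parse
#' problems are reported with file line numbers.
#'
#' @param path TSV file path.
#' @return A [site_energy_trace()], or a list of them (one per replicate)
#'   when a `replicate` column with several ids is present.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    ht_error("ht_parse_error", sprintf("no such file: '%s'", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  cols <- names(raw)
  if (!"time_ps" %in% cols) {
    ht_error("ht_parse_error",
             sprintf("'%s': missing required column 'time_ps' (found: %s)",
                     path, paste(cols, collapse = ", ")))
  }
  two <- all(c("e_donor_eV", "e_acceptor_eV") %in% cols)
  if (!two && length(setdiff(cols, c("time_ps", "replicate"))) != 1L) {
    ht_error("ht_parse_error",
             sprintf(paste("'%s': expected columns time_ps, e_donor_eV,",
                           "e_acceptor_eV [, replicate] or time_ps plus one",
                           "value column"), path))
  }
  num_cols <- setdiff(cols, "replicate")
  num <- list()
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !raw[[cn]] %in% c("NA", ""))
    if (length(bad)) {
      ht_error("ht_parse_error",
               sprintf("'%s': non-numeric value '%s' in column '%s' at line %d",
                       path, raw[[cn]][bad[1]], cn, bad[1] + 1L))
    }
    if (anyNA(v)) {
      ht_error("ht_parse_error",
               sprintf("'%s': missing value in column '%s' at line %d",
                       path, cn, which(is.na(v))[1] + 1L))
    }
    num[[cn]] <- v
  }
  build <- function(idx, rep_id = NA) {
    if (two) {
      site_energy_trace(num$time_ps[idx],
                        e_donor = num$e_donor_eV[idx],
                        e_acceptor = num$e_acceptor_eV[idx],
                        replicate = rep_id)
    } else {
      vc <- setdiff(num_cols, "time_ps")
      site_energy_trace(num$time_ps[idx], value = num[[vc]][idx],
                        replicate = rep_id, channel = vc)
    }
  }
  if ("replicate" %in% cols && length(unique(raw$replicate)) > 1L) {
    ids <- unique(raw$replicate)
    lapply(ids, function(id) build(which(raw$replicate == id), id))
  } else {
    rep_id <- if ("replicate" %in% cols) raw$replicate[1] else NA
    build(seq_along(num$time_ps), rep_id)
  }
}

#' Write a site-energy trace to TSV
#'
#' Inverse of [read_trace()]: writes the trace's channels under the
#' standard column names (`time_ps`, then `e_donor_eV`/`e_acceptor_eV` or
#' the single channel name), with a `replicate` column when the trace
#' carries a replicate id. Values survive a round trip at the printed
#' precision (15 significant digits).
#'
#' @param trace A [site_energy_trace()], or a list of replicates (written
#'   stacked with their `replicate` ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  traces <- if (inherits(trace, "site_energy_trace")) list(trace) else trace
  tabs <- lapply(traces, function(tr) {
    df <- data.frame(time_ps = tr$time_ps)
    if (is_two_channel(tr)) {
      df$e_donor_eV <- tr$e_donor
      df$e_acceptor_eV <- tr$e_acceptor
    } else {
      df[[tr$channels[[1]]]] <- tr[[tr$channels[[1]]]]
    }
    if (!is.na(tr$replicate)) df$replicate <- tr$replicate
    df
  })
  df <- do.call(rbind, tabs)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an acf_result or spectrum_result to TSV
#'
#' Two-column tab-separated output: `lag_ps`/`acf` for ACF results,
#' `wavenumber_cm1`/`power` for spectra.
#'
#' @param x An `acf_result` or `spectrum_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  df <- if (inherits(x, "acf_result")) {
    data.frame(lag_ps = x$lag_ps, acf = x$acf)
  } else if (inherits(x, "spectrum_result")) {
    data.frame(wavenumber_cm1 = x$wavenumber_cm1, power = x$power)
  } else {
    ht_error("ht_invalid_parameter",
             "`x` must be an acf_result or spectrum_result")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
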