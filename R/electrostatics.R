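#' Point-charge snapshot with site membership
#'
#' One frame of a point-charge trajectory: atomic coordinates (Angstrom),
#' partial charges (units of e), and a map assigning atoms to named
#' nucleobase sites. The total charge of the frame is reported but not
#' constrained (an oxidized strand plus counterions need not be neutral).
#'
#' @param coords Numeric `n x 3` matrix of coordinates, Angstrom.
#' @param charges Numeric vector of partial charges, e.
#' @param sites Named list: site label -> integer vector of 1-based atom
#'   ids (matching row order in `coords`).
#' @param model Optional model index (frame number).
#' @param atom_names,res_names,res_ids Optional atom metadata (used when
#'   writing PQR).
#' @param radii Optional per-atom radii, Angstrom (PQR column; never used in
#'   the potential, carried for round-tripping).
#' @return A `charge_snapshot` object.
#' @export
charge_snapshot <- function(coords, charges, sites = list(), model = NA,
                            atom_names = NULL, res_names = NULL,
                            res_ids = NULL, radii = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || !is.numeric(coords) || !all(is.finite(coords))) {
    ht_error("ht_invalid_parameter",
             "`coords` must be a finite numeric n x 3 matrix")
  }
  n <- nrow(coords)
  charges <- as.numeric(charges)
  if (length(charges) != n || !all(is.finite(charges))) {
    ht_error("ht_invalid_parameter",
             "`charges` must be finite and match the atom count")
  }
  for (lab in names(sites)) {
    ids <- sites[[lab]]
    if (!length(ids) || any(ids < 1L | ids > n | ids != round(ids))) {
      ht_error("ht_invalid_parameter",
               sprintf("site '%s' has atom ids outside 1..%d", lab, n))
    }
  }
  structure(
    list(coords = coords, charges = charges, sites = sites, model = model,
         atom_names = atom_names %||% rep("X", n),
         res_names = res_names %||% rep("UNK", n),
         res_ids = res_ids %||% rep(1L, n),
         radii = radii %||% rep(1.5, n),
         total_charge = sum(charges)),
    class = "charge_snapshot"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.charge_snapshot <- function(x, ...) {
  cat(sprintf("charge_snapshot: %d atoms, total charge %+.4g e",
              nrow(x$coords), x$total_charge))
  if (!is.na(x$model)) cat(sprintf(" (model %s)", x$model))
  cat("\n")
  if (length(x$sites)) {
    cat("  sites:", paste(sprintf("%s[%d]", names(x$sites),
                                  lengths(x$sites)), collapse = ", "), "\n")
  }
  invisible(x)
}

site_atom_ids <- function(snapshot, site) {
  ids <- snapshot$sites[[site]]
  if (is.null(ids)) {
    ht_error("ht_invalid_parameter", sprintf("unknown site '%s'", site))
  }
  ids
}

#' Geometric midpoint of a nucleobase site
#'
#' The unweighted arithmetic mean of the member atoms' coordinates — the
#' probe point at which the site's electrostatic environment is evaluated.
#' All atoms count equally (no mass or charge weighting).
#'
#' @param snapshot A [charge_snapshot()].
#' @param site Site label.
#' @return Numeric length-3 point, Angstrom.
#' @export
site_midpoint <- function(snapshot, site) {
  ids <- site_atom_ids(snapshot, site)
  colMeans(snapshot$coords[ids, , drop = FALSE])
}

#' Coulomb potential of the point-charge environment at a probe point
#'
#' Bare Coulomb sum `V = ke * sum_i q_i / r_i` with
#' `ke = 14.399645 V*Angstrom/e`, over every atom not belonging to the
#' excluded site (the probed site's own atoms are unphysical sources for
#' its environment probe). No periodic images and no reaction field; a
#' spherical cutoff may be supplied for experiments but is off by default.
#'
#' @param snapshot A [charge_snapshot()].
#' @param point Numeric length-3 probe point, Angstrom.
#' @param exclude_site Site label whose atoms are excluded (`NULL` for
#'   none).
#' @param cutoff Optional spherical cutoff radius, Angstrom (`Inf` = none).
#' @return Potential, V.
#' @examples
#' snap <- charge_snapshot(rbind(c(14.399645, 0, 0)), charges = 1)
#' coulomb_potential(snap, c(0, 0, 0))   # exactly 1 V
#' @export
coulomb_potential <- function(snapshot, point, exclude_site = NULL,
                              cutoff = Inf) {
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point))) {
    ht_error("ht_invalid_parameter", "`point` must be a finite length-3 vector")
  }
  keep <- rep(TRUE, nrow(snapshot$coords))
  if (!is.null(exclude_site)) {
    keep[site_atom_ids(snapshot, exclude_site)] <- FALSE
  }
  if (!any(keep)) return(0)
  dx <- sweep(snapshot$coords[keep, , drop = FALSE], 2, point)
  r <- sqrt(rowSums(dx^2))
  if (any(r < 1e-6)) {
    ht_error("ht_singularity_error",
             sprintf("atom %d coincides with the probe point (r = %.2e A)",
                     which(keep)[which.min(r)], min(r)))
  }
  inside <- r <= cutoff
  ht_constants$ke_VA * sum(snapshot$charges[keep][inside] / r[inside])
}

#' Electrostatic potential time series at a site midpoint
#'
#' For each snapshot, evaluates the Coulomb potential of the environment at
#' that frame's site midpoint (the site's own atoms excluded). The result
#' feeds the trajectory statistics: [replicate_average()],
#' [fourier_spectrum()].
#'
#' @param snapshots List of [charge_snapshot()] frames with a consistent
#'   site map.
#' @param site Site label to probe.
#' @param times Time stamps for the frames (default frame index); units are
#'   the caller's (fs for the fast potential signals).
#' @param time_unit_ps Length of one `times` unit in ps (default `1e-3`,
#'   i.e. `times` in fs).
#' @param cutoff Optional spherical cutoff, Angstrom.
#' @return A single-channel [site_energy_trace()] (channel
#'   `"potential_V"`), with times converted to ps.
#' @export
potential_trace <- function(snapshots, site, times = NULL,
                            time_unit_ps = 1e-3, cutoff = Inf) {
  if (inherits(snapshots, "charge_snapshot")) snapshots <- list(snapshots)
  if (length(snapshots) < 2L) {
    ht_error("ht_invalid_parameter", "need >= 2 snapshots for a trace")
  }
  for (s in snapshots) site_atom_ids(s, site)
  v <- vapply(snapshots, function(s) {
    coulomb_potential(s, site_midpoint(s, site), exclude_site = site,
                      cutoff = cutoff)
  }, numeric(1))
  if (is.null(times)) times <- seq_along(snapshots) - 1
  site_energy_trace(times * time_unit_ps, value = v, channel = "potential_V")
}

#' Read a (multi-model) PQR trajectory
#'
#' Reads PQR — the PDB-like format whose occupancy and B-factor columns
#' carry per-atom partial charge (e) and radius (Angstrom) — into a list of
#' [charge_snapshot()] frames, one per `MODEL` block (a file without
#' `MODEL` records yields one frame). Atom order is preserved and site maps
#' use 1-based positions in that order. Parsing is delegated to
#' `bio3d::read.pqr()`.
#'
#' @param path PQR file path.
#' @param sites Named list of site memberships (e.g. from
#'   [read_sites_json()]) attached to every frame.
#' @return List of `charge_snapshot` objects.
#' @export
read_pqr <- function(path, sites = list()) {
  if (!file.exists(path)) {
    ht_error("ht_parse_error", sprintf("no such file: '%s'", path))
  }
  txt <- readLines(path)
  n_models <- sum(grepl("^MODEL", txt))
  multi <- n_models > 1L
  counts <- integer(0)
  if (multi) {
    # bio3d requires equal atom counts per model; check first for a clear error
    starts <- grep("^MODEL", txt)
    ends <- grep("^ENDMDL", txt)
    if (length(ends) != length(starts)) {
      ht_error("ht_structural_error",
               sprintf("'%s': %d MODEL but %d ENDMDL records", path,
                       length(starts), length(ends)))
    }
    counts <- mapply(function(a, b) sum(grepl("^(ATOM|HETATM)", txt[a:b])),
                     starts, ends)
    if (length(unique(counts)) != 1L) {
      ht_error("ht_structural_error",
               sprintf("'%s': inconsistent atom counts across models (%s)",
                       path, paste(unique(counts), collapse = ", ")))
    }
  }
  pdb <- suppressWarnings(
    utils::capture.output(
      p <- bio3d::read.pqr(path, multi = multi, verbose = FALSE)
    )
  )
  atom <- p$atom
  xyz <- p$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    charge_snapshot(
      coords = matrix(xyz[m, ], ncol = 3, byrow = TRUE),
      charges = atom$o,
      sites = sites, model = m,
      atom_names = atom$elety, res_names = atom$resid,
      res_ids = atom$resno, radii = atom$b
    )
  })
}

#' Write snapshots as a multi-model PQR file
#'
#' Inverse of [read_pqr()]: writes each [charge_snapshot()] as one `MODEL`
#' block with charge and radius in the PQR columns (via
#' `bio3d::write.pqr()`). Coordinates and charges survive a round trip at
#' the format's printed precision (1e-3 Angstrom / 1e-2 e as written by
#' bio3d; see [read_pqr()]).
#'
#' @param snapshots A `charge_snapshot` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(snapshots, path) {
  if (inherits(snapshots, "charge_snapshot")) snapshots <- list(snapshots)
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pqr")
  on.exit(unlink(tmp), add = TRUE)
  for (m in seq_along(snapshots)) {
    s <- snapshots[[m]]
    bio3d::write.pqr(xyz = as.numeric(t(s$coords)),
                     resno = s$res_ids, resid = s$res_names,
                     eleno = seq_len(nrow(s$coords)), elety = s$atom_names,
                     o = s$charges, b = s$radii, file = tmp)
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(grep("^(ATOM|HETATM)", readLines(tmp), value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a site-membership map from JSON
#'
#' The site map is a JSON object `{site label: [atom ids]}` with 1-based
#' ids referring to atom order in the companion PQR file.
#'
#' @param path JSON file path.
#' @return Named list of integer vectors.
#' @export
read_sites_json <- function(path) {
  sites <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(sites) || is.null(names(sites)) || any(names(sites) == "")) {
    ht_error("ht_parse_error",
             sprintf("'%s': expected an object of named atom-id arrays", path))
  }
  lapply(sites, as.integer)
}
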