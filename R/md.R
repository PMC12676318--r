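#' Atom selections on trajectories
#'
#' Resolves a selection to atom indices: an integer vector passes through,
#' a logical vector is `which()`ed, and a character vector selects by atom
#' name (e.g. `c("N", "CA", "C", "O")` for the backbone).
#'
#' @param traj A [trajectory()].
#' @param selection Integer, logical or character selection (default:
#'   backbone atom names).
#' @return Integer atom indices.
#' @export
select_atoms <- function(traj, selection = c("N", "CA", "C", "O")) {
  idx <- if (is.character(selection)) {
    which(traj$atoms$name %in% selection)
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
  if (!length(idx)) abort("selection matches no atoms")
  if (any(idx < 1 | idx > nrow(traj$atoms))) abort("selection out of range")
  idx
}

#' Superposed trajectory RMSD time series
#'
#' Per frame, Kabsch-superposes the selected atoms onto the reference
#' frame and reports the RMSD over the selection -- the standard
#' backbone-stability readout of an MD simulation.
#'
#' @param traj A [trajectory()].
#' @param ref_frame Reference frame index (default 1).
#' @param selection See [select_atoms()].
#' @return A tibble with class `traj_rmsd`: `time_ns`, `rmsd` (Angstrom).
#' @export
traj_rmsd <- function(traj, ref_frame = 1L, selection = c("N", "CA", "C", "O")) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- select_atoms(traj, selection)
  ref <- traj$frames[[ref_frame]][idx, , drop = FALSE]
  vals <- vapply(traj$frames, function(f) {
    kabsch_superpose(ref, f[idx, , drop = FALSE])$rmsd
  }, numeric(1))
  out <- tibble(time_ns = traj$times, rmsd = vals)
  class(out) <- c("traj_rmsd", class(out))
  out
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each selected atom about its own mean
#' position, `sqrt(mean_t ||r_t - <r>||^2)`, averaged within residues.
#' With `align = TRUE` frames are first superposed (over the selection)
#' onto the first frame and then onto the mean structure, removing global
#' rigid motion before fluctuations are measured.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param selection See [select_atoms()].
#' @param align Remove global rigid motion first (default `TRUE`).
#' @return A tibble with class `traj_rmsf`: `resid`, `resname`, `rmsf`
#'   (Angstrom).
#' @export
traj_rmsf <- function(traj, selection = c("N", "CA", "C", "O"), align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2) abort("RMSF needs at least 2 frames")
  idx <- select_atoms(traj, selection)
  coords <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  if (align) {
    ref <- coords[[1]]
    coords <- lapply(coords, function(f) kabsch_superpose(ref, f)$aligned)
    mean_str <- Reduce(`+`, coords) / length(coords)
    coords <- lapply(coords, function(f) kabsch_superpose(mean_str, f)$aligned)
  }
  mean_str <- Reduce(`+`, coords) / length(coords)
  sq <- Reduce(`+`, lapply(coords, function(f) rowSums((f - mean_str)^2))) /
    length(coords)
  per_atom <- tibble(
    resid = traj$atoms$resid[idx],
    resname = traj$atoms$resname[idx],
    rmsf = sqrt(sq)
  )
  out <- per_atom |>
    group_by(.data$resid, .data$resname) |>
    summarise(rmsf = mean(.data$rmsf), .groups = "drop") |>
    arrange(.data$resid)
  class(out) <- c("traj_rmsf", class(out))
  out
}

#' Geometric hydrogen-bond criteria
#'
#' The default criterion is distance-only: donor--acceptor separation of at
#' most 3.5 Angstrom. An optional D-H...A angle cutoff can be enabled
#' (conventionally 150 degrees); it requires hydrogen positions and is off
#' by default.
#'
#' @param max_distance Maximum donor--acceptor distance (Angstrom).
#' @param min_angle Optional minimum D-H...A angle (degrees) or `NULL`.
#' @return A list with class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = NULL) {
  assert_scalar_finite(max_distance, "max_distance")
  if (max_distance <= 0) abort("`max_distance` must be positive")
  if (!is.null(min_angle)) assert_scalar_finite(min_angle, "min_angle")
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Per-frame hydrogen-bond counts
#'
#' Counts donor/acceptor pairs satisfying the geometric criterion in each
#' frame. With an angle cutoff enabled, `hydrogens` must map each donor to
#' its hydrogen atom index so the D-H...A angle can be measured.
#'
#' @param traj A [trajectory()].
#' @param donors,acceptors Atom index vectors (non-empty; a pair with the
#'   same atom on both sides is ignored).
#' @param criteria An [hbond_criteria()].
#' @param hydrogens Optional integer vector parallel to `donors`.
#' @return A tibble with class `hbond_counts`: `time_ns`, `n_hbonds`.
#' @export
hbond_counts <- function(traj, donors, acceptors, criteria = hbond_criteria(),
                         hydrogens = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(criteria, "hbond_criteria"))
  if (!length(donors) || !length(acceptors)) {
    abort("donor and acceptor selections must be non-empty")
  }
  if (!is.null(criteria$min_angle) && is.null(hydrogens)) {
    abort("the angle criterion needs `hydrogens` (one H index per donor)")
  }
  pairs <- expand.grid(d = seq_along(donors), a = seq_along(acceptors))
  pairs <- pairs[donors[pairs$d] != acceptors[pairs$a], , drop = FALSE]
  counts <- vapply(traj$frames, function(f) {
    dd <- f[donors[pairs$d], , drop = FALSE]
    aa <- f[acceptors[pairs$a], , drop = FALSE]
    dist <- sqrt(rowSums((dd - aa)^2))
    ok <- dist <= criteria$max_distance
    if (!is.null(criteria$min_angle)) {
      hh <- f[hydrogens[pairs$d], , drop = FALSE]
      v1 <- dd - hh; v2 <- aa - hh
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      ok <- ok & ang >= criteria$min_angle
    }
    sum(ok)
  }, numeric(1))
  out <- tibble(time_ns = traj$times, n_hbonds = as.integer(counts))
  class(out) <- c("hbond_counts", class(out))
  out
}

#' Mean total short-range interaction energy
#'
#' Mean over frames of the Coul-SR + LJ-SR sum (kJ/mol): the scalar each
#' simulated complex is summarized by before energy-ratio comparison.
#'
#' @param series An [energy_series()].
#' @return Mean total energy (kJ/mol).
#' @export
energy_summary <- function(series) {
  if (!inherits(series, "energy_series")) {
    series <- energy_series(series$coul_sr, series$lj_sr, series$time_ns)
  }
  mean(series$coul_sr + series$lj_sr)
}

#' Interaction-energy ratio
#'
#' `|e_system| / |e_reference|`, rounded half-even to 4 decimals -- the
#' scale-free comparison of a candidate complex's mean interaction energy
#' against the reference ligand's.
#'
#' @param e_system,e_reference Mean total energies (kJ/mol), both nonzero
#'   and of the same sign.
#' @return The ratio, rounded to 4 decimals.
#' @examples
#' energy_ratio(-859009.6, -858589.2)   # 1.0005
#' @export
energy_ratio <- function(e_system, e_reference) {
  assert_scalar_finite(e_system, "e_system")
  assert_scalar_finite(e_reference, "e_reference")
  if (e_reference == 0) abort("reference energy must be nonzero")
  if (e_system == 0) abort("system energy must be nonzero")
  if (sign(e_system) != sign(e_reference)) {
    abort("energies must have the same sign for a meaningful ratio")
  }
  round(abs(e_system) / abs(e_reference), 4)
}
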