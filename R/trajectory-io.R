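#' Trajectories
#'
#' A trajectory is an ordered list of coordinate frames (N x 3 matrices, in
#' Angstrom) over a fixed atom table, with strictly increasing frame times
#' in nanoseconds.
#'
#' @param frames A list of N x 3 numeric matrices, all with the same N.
#' @param atoms A data frame with per-atom metadata: `name` (atom name),
#'   `element`, `resid` (1-based residue index) and `resname`.
#' @param times Numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `0, 1, 2, ...`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, atoms, times = NULL) {
  if (!length(frames)) abort("a trajectory needs at least one frame")
  atoms <- as_tibble(atoms)
  for (col in c("name", "element", "resid", "resname")) {
    if (!col %in% names(atoms)) abort(paste0("`atoms` needs a `", col, "` column"))
  }
  n <- nrow(atoms)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3) abort("all frames must be N x 3 over the atom table")
    if (!all(is.finite(f))) abort("frame coordinates must be finite")
    dimnames(f) <- NULL
    f
  })
  times <- times %||% as.numeric(seq_along(frames) - 1)
  if (length(times) != length(frames)) abort("one time per frame required")
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  structure(list(frames = frames, atoms = atoms, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames x ", nrow(x$atoms), " atoms, ",
      "t = [", x$times[1], ", ", x$times[length(x$times)], "] ns\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Read a trajectory from multi-model PDB or multi-frame XYZ
#'
#' Multi-model PDB files are read through bio3d (one MODEL per frame);
#' XYZ files use the plain multi-frame convention (atom count, comment,
#' element + coordinates). Engine-native binary trajectory formats are out
#' of scope.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param times Optional frame times (ns).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"), times = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "pdb"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atoms <- tibble(
      name = pdb$atom$elety,
      element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                       substr(trimws(pdb$atom$elety), 1, 1), trimws(pdb$atom$elesy)),
      resid = as.integer(pdb$atom$resno),
      resname = pdb$atom$resid
    )
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    })
    trajectory(frames, atoms, times)
  } else {
    read_xyz_trajectory(path, times)
  }
}

# Plain multi-frame XYZ: no installed package reads this stacked variant,
# so a minimal reader lives here.
read_xyz_trajectory <- function(path, times = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  elements <- NULL
  pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) abort(paste0("bad XYZ atom count at line ", pos))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) {
      elements <- el
    } else if (!identical(elements, el)) {
      abort("XYZ frames disagree on atom identity")
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  atoms <- tibble(name = elements, element = elements,
                  resid = seq_along(elements), resname = "UNK")
  trajectory(frames, atoms, times)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$atoms)
  for (k in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d t=%.6f", k, traj$times[k]), con)
    f <- traj$frames[[k]]
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$element, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a per-frame interaction-energy series
#'
#' Expects a whitespace- or comma-delimited file with columns
#' `time_ns, coul_sr, lj_sr` (header optional, `#` comments ignored):
#' short-range Coulomb and Lennard-Jones protein--ligand interaction-energy
#' terms in kJ/mol per frame.
#'
#' @param path File path.
#' @return A tibble with columns `time_ns`, `coul_sr`, `lj_sr`.
#' @export
read_energy_series <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  first <- strsplit(trimws(lines[1]), "[,[:space:]]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(normalize_minus(first)))))
  if (has_header) lines <- lines[-1]
  vals <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), function(p) {
    as.numeric(normalize_minus(p))
  })
  m <- do.call(rbind, vals)
  if (ncol(m) < 3) abort("energy series needs columns time_ns, coul_sr, lj_sr")
  energy_series(coul_sr = m[, 2], lj_sr = m[, 3], times = m[, 1])
}

#' Construct an interaction-energy series
#'
#' @param coul_sr Per-frame short-range Coulomb energies (kJ/mol).
#' @param lj_sr Per-frame short-range Lennard-Jones energies (kJ/mol).
#' @param times Frame times (ns).
#' @return A tibble with class `energy_series`.
#' @export
energy_series <- function(coul_sr, lj_sr, times = NULL) {
  if (length(coul_sr) != length(lj_sr)) {
    abort("coul_sr and lj_sr must have equal length")
  }
  if (!length(coul_sr)) abort("energy series must be non-empty")
  times <- times %||% as.numeric(seq_along(coul_sr) - 1)
  if (length(times) != length(coul_sr)) abort("one time per frame required")
  out <- tibble(time_ns = as.numeric(times), coul_sr = as.numeric(coul_sr),
                lj_sr = as.numeric(lj_sr))
  class(out) <- c("energy_series", class(out))
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}
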