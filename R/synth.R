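#' Synthetic compound table with planted quadrant membership
#'
#' Draws `n` compounds with affinities ~ Uniform(-11.5, -6.5) kcal/mol and
#' LD50 ~ Uniform(2.3, 3.0) mol/kg, then adjusts draws so that exactly
#' `round(n * frac_quadrant_pass)` satisfy the quadrant rule against the
#' reference (affinity at least as favorable AND LD50 at least as safe).
#' The planted label is returned in `truth_pass`. Same seed, same table.
#'
#' @param n Number of compounds.
#' @param frac_quadrant_pass Fraction in `[0, 1]` that must pass.
#' @param reference List or one-row data frame with `affinity_kcal_mol`
#'   and `ld50_mol_kg` strictly inside the draw ranges.
#' @param seed Integer seed.
#' @return A tibble: `id`, `affinity_kcal_mol`, `ld50_mol_kg`,
#'   `truth_pass`.
#' @examples
#' ref <- list(id = "REF", affinity_kcal_mol = -8.5, ld50_mol_kg = 2.713)
#' tab <- gen_compound_table(199, 12 / 199, ref, seed = 42)
#' sum(tab$truth_pass)   # 12
#' @export
gen_compound_table <- function(n, frac_quadrant_pass, reference, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1")
  if (frac_quadrant_pass < 0 || frac_quadrant_pass > 1) {
    abort("`frac_quadrant_pass` must be in [0, 1]")
  }
  ref_aff <- as.numeric(reference$affinity_kcal_mol[1])
  ref_ld <- as.numeric(reference$ld50_mol_kg[1])
  assert_scalar_finite(ref_aff, "reference$affinity_kcal_mol")
  assert_scalar_finite(ref_ld, "reference$ld50_mol_kg")
  if (ref_aff <= -11.5 + 0.05 || ref_aff >= -6.5 - 0.05 ||
      ref_ld <= 2.3 + 0.01 || ref_ld >= 3.0 - 0.01) {
    abort("reference must lie strictly inside the draw ranges (-11.5, -6.5) x (2.3, 3.0)")
  }
  k <- round(n * frac_quadrant_pass)
  with_stream_seed(seed, "gen_compound_table", {
    pass <- rep(FALSE, n)
    pass[sample.int(n, k)] <- TRUE
    aff <- runif(n, -11.5, -6.5)
    ld <- runif(n, 2.3, 3.0)
    # passers: both axes strictly on the favorable side of the reference
    aff[pass] <- runif(k, -11.5, ref_aff - 0.01)
    ld[pass] <- runif(k, ref_ld + 0.001, 3.0)
    # failers: violate at least one axis strictly
    fail <- which(!pass)
    axis <- sample(c("aff", "ld", "both"), length(fail), replace = TRUE)
    aff[fail[axis != "ld"]] <-
      runif(sum(axis != "ld"), ref_aff + 0.01, -6.5)
    ld[fail[axis != "aff"]] <-
      runif(sum(axis != "aff"), 2.3, ref_ld - 0.001)
    tibble(
      id = sprintf("SYN-%06d", seq_len(n)),
      affinity_kcal_mol = round(aff, 3),
      ld50_mol_kg = round(ld, 4),
      truth_pass = pass
    )
  })
}

#' Synthetic active/decoy score sets with known expected AUC
#'
#' Actives ~ Normal(mu - delta, sigma) and decoys ~ Normal(mu, sigma) on
#' the lower-is-better docking-affinity convention, so the population AUC
#' has the closed form `pnorm(delta / (sigma * sqrt(2)))`, recorded as
#' truth.
#'
#' @param n_act,n_dec Set sizes (both >= 1).
#' @param delta Mean separation (kcal/mol; positive favors actives).
#' @param sigma Common standard deviation.
#' @param mu Decoy mean (default -7.5 kcal/mol).
#' @param seed Integer seed.
#' @return A list with class `scored_set`: `active`, `decoy`,
#'   `expected_auc`, and the parameters.
#' @export
gen_score_sets <- function(n_act, n_dec, delta, sigma, mu = -7.5, seed = 1L) {
  if (n_act < 1 || n_dec < 1) abort("`n_act` and `n_dec` must be >= 1")
  if (sigma < 0) abort("`sigma` must be non-negative")
  with_stream_seed(seed, "gen_score_sets", {
    structure(list(
      active = stats::rnorm(n_act, mu - delta, sigma),
      decoy = stats::rnorm(n_dec, mu, sigma),
      expected_auc = if (sigma > 0) stats::pnorm(delta / (sigma * sqrt(2)))
                     else as.numeric(delta > 0) + 0.5 * (delta == 0),
      delta = delta, sigma = sigma, mu = mu
    ), class = "scored_set")
  })
}

# idealized flat hexagon of carbons, aromatic (order-4) ring bonds
benzene_graph <- function() {
  ang <- (0:5) * pi / 3
  coords <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  bonds <- tibble(i = 1:6, j = c(2:6, 1L), order = 4)
  molecule_graph(
    atoms = tibble(element = rep("C", 6), charge = 0L),
    bonds = bonds, coords = coords, name = "benzene"
  )
}

# para-disubstituted benzene: F at position 1, Cl at position 4
para_graph <- function() {
  b <- benzene_graph()
  coords <- rbind(b$coords,
                  c(2.74, 0, 0),    # F along the C1 direction
                  c(-3.16, 0, 0))   # Cl along the C4 direction
  molecule_graph(
    atoms = tibble(element = c(rep("C", 6), "F", "Cl"), charge = 0L),
    bonds = rbind(b$bonds, tibble(i = c(1L, 4L), j = c(7L, 8L), order = 1)),
    coords = coords, name = "para_disubstituted"
  )
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Toy conformer pairs with known pose-comparison truth
#'
#' Builds an idealized reference conformer and a rigidly transformed copy.
#' Kinds: `"benzene"` (6 aromatic carbons, 12 graph automorphisms),
#' `"para_disubstituted"` (F/Cl para pair, 2 automorphisms), `"rgz_like"`
#' (the bundled rosiglitazone 3D conformer). The transform is a list with
#' `angle_deg` (rotation about z through the centroid, default 0),
#' `translation` (length 3, default zero), or the string `"random"` for a
#' seeded random rigid motion.
#'
#' Truth: superposed symmetry-RMSD is always 0 for a rigid copy. The
#' in-place value is recorded when it is knowable without search: it is
#' the translation norm when the rotation is a symmetry of the molecule
#' (multiples of 60 degrees for benzene, 180 for the para compound, 0 for
#' anything), and `NA` otherwise.
#'
#' @param kind One of `"benzene"`, `"para_disubstituted"`, `"rgz_like"`.
#' @param transform Transform spec (see above).
#' @param seed Integer seed (used only by `"random"`).
#' @return A list with class `conformer_pair`: `ref`, `probe`, `truth`
#'   (list: `rmsd_superposed`, `rmsd_in_place`, `n_automorphisms`).
#' @export
gen_toy_conformers <- function(kind = c("benzene", "para_disubstituted", "rgz_like"),
                               transform = list(), seed = 1L) {
  kind <- match.arg(kind)
  ref <- switch(kind,
    benzene = benzene_graph(),
    para_disubstituted = para_graph(),
    rgz_like = read_structures(extdata_path("rgz_synthetic.sdf"), format = "sdf")[[1]]
  )
  n_auto <- switch(kind, benzene = 12L, para_disubstituted = 2L, rgz_like = NA_integer_)
  center <- colMeans(ref$coords)
  if (identical(transform, "random")) {
    tr <- with_stream_seed(seed, "gen_toy_conformers", {
      list(R = random_rotation(), t = stats::runif(3, -5, 5))
    })
    R <- tr$R; t <- tr$t; angle <- NA_real_
  } else {
    angle <- transform$angle_deg %||% 0
    R <- rotation_about_z(angle)
    t <- transform$translation %||% c(0, 0, 0)
  }
  probe_coords <- sweep(sweep(ref$coords, 2, center) %*% t(R), 2, center + t, "+")
  probe <- conformer(ref, probe_coords)
  period <- switch(kind, benzene = 60, para_disubstituted = 180, rgz_like = 360)
  in_place <- if (!is.na(angle) && isTRUE(all.equal(angle %% period, 0))) {
    sqrt(sum(t^2))
  } else {
    NA_real_
  }
  structure(list(
    ref = ref, probe = probe,
    truth = list(rmsd_superposed = 0, rmsd_in_place = in_place,
                 n_automorphisms = n_auto)
  ), class = "conformer_pair")
}

#' Synthetic trajectory with known per-residue RMSF
#'
#' One CA atom per residue placed on an extended chain, each frame
#' perturbed by isotropic Gaussian noise with per-residue standard
#' deviation `sigma_profile` (recycled across residues). No global rigid
#' motion is added, so the truth RMSF per residue is `sigma * sqrt(3)`
#' exactly in expectation.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_atoms Number of atoms/residues.
#' @param sigma_profile Per-residue noise sd (Angstrom), recycled.
#' @param seed Integer seed.
#' @return A list with class `synthetic_trajectory`: `trajectory` (a
#'   [trajectory()]) and `truth` (tibble: `resid`, `sigma`, `rmsf`).
#' @export
gen_trajectory <- function(n_frames, n_atoms, sigma_profile = 0.5, seed = 1L) {
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  if (n_atoms < 1) abort("`n_atoms` must be >= 1")
  if (any(sigma_profile < 0)) abort("`sigma_profile` must be non-negative")
  sigma <- rep_len(sigma_profile, n_atoms)
  base <- cbind(3.8 * seq_len(n_atoms), 0, 0)
  atoms <- tibble(
    name = rep("CA", n_atoms),
    resid = seq_len(n_atoms),
    resname = rep("ALA", n_atoms),
    element = rep("C", n_atoms)
  )
  with_stream_seed(seed, "gen_trajectory", {
    frames <- lapply(seq_len(n_frames), function(f) {
      base + matrix(stats::rnorm(3 * n_atoms, 0, sigma), n_atoms, 3)
    })
    structure(list(
      trajectory = trajectory(frames, atoms),
      truth = tibble(resid = seq_len(n_atoms), sigma = sigma,
                     rmsf = sigma * sqrt(3))
    ), class = "synthetic_trajectory")
  })
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic target/template sequence pair with planted mismatches
#'
#' Draws a random amino-acid target of the given length and copies it into
#' a template with `n_mismatch` planted substitutions at recorded interior
#' positions (kept away from the termini so an end-gap-free alignment
#' cannot clip them). An optional `window = c(start, end)` truncates the
#' template to emulate partial coverage. Truth identity over the aligned
#' region is exact by construction.
#'
#' @param length Sequence length.
#' @param n_mismatch Number of substitutions (`<= length`).
#' @param window Optional template window `c(start, end)` in target
#'   coordinates.
#' @param seed Integer seed.
#' @return A list with class `sequence_pair`: `target`, `template`,
#'   `truth` (list: `positions`, `identity`, `coverage`).
#' @examples
#' sp <- gen_sequences(272, 3, seed = 7)
#' sp$truth$identity   # 98.9
#' @export
gen_sequences <- function(length, n_mismatch, window = NULL, seed = 1L) {
  if (length < 1) abort("`length` must be >= 1")
  if (n_mismatch > length) abort("`n_mismatch` must be <= `length`")
  if (!is.null(window)) {
    if (window[1] < 1 || window[2] > length || window[1] > window[2]) {
      abort("`window` must satisfy 1 <= start <= end <= length")
    }
  }
  lo <- if (is.null(window)) 1L else as.integer(window[1])
  hi <- if (is.null(window)) length else as.integer(window[2])
  # interior margin keeps planted mismatches clear of alignment end-clipping
  margin <- min(10L, max(0L, (hi - lo - n_mismatch) %/% 2))
  pool <- seq.int(lo + margin, hi - margin)
  if (n_mismatch > base::length(pool)) {
    abort("window too small for the requested number of mismatches")
  }
  with_stream_seed(seed, "gen_sequences", {
    target <- sample(AA_ALPHABET, length, replace = TRUE)
    template <- target
    positions <- sort(sample(pool, n_mismatch))
    for (p in positions) {
      template[p] <- sample(setdiff(AA_ALPHABET, target[p]), 1)
    }
    template <- template[lo:hi]
    aligned <- hi - lo + 1L
    structure(list(
      target = paste(target, collapse = ""),
      template = paste(template, collapse = ""),
      truth = list(
        positions = positions,
        identity = round(100 * (aligned - n_mismatch) / aligned, 2),
        coverage = round(100 * aligned / length, 2)
      )
    ), class = "sequence_pair")
  })
}
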