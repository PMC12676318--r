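#' Global end-gap-free sequence alignment with identity and coverage
#'
#' Aligns a target (model) sequence against a template with an end-gap-free
#' global alignment (terminal gaps free), BLOSUM62 and affine gap
#' penalties. Free end gaps matter because a template frequently covers
#' only part of the target, and coverage is reported as the percentage of
#' target residues inside the aligned region. Identity is
#' matches / aligned (non-gap) columns x 100, reported to 2 decimals.
#'
#' @param target,template Amino-acid sequences (plain strings).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 / 0.5).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return A list with class `alignment_result`: `identity`, `coverage`,
#'   `n_matches`, `n_mismatches`, `mismatches` (tibble: `target_pos`,
#'   `target_res`, `template_res`), and `aligned` (tibble of aligned
#'   column positions, 1-based in each sequence, `NA` at gaps).
#' @export
align_sequences <- function(target, template, gap_open = 10, gap_extend = 0.5,
                            matrix = "BLOSUM62") {
  target <- toupper(as.character(target)[1])
  template <- toupper(as.character(template)[1])
  if (!nzchar(target) || !nzchar(template)) abort("sequences must be non-empty")
  submat <- get_substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(target),
    subject = Biostrings::AAString(template),
    type = "overlap", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # 1-based positions in the original sequences; overlap alignments clip
  # the unaligned flanks, so offset by the alignment start
  p0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  tpos <- ifelse(pat == "-", NA_integer_, p0 + cumsum(pat != "-"))
  spos <- ifelse(sub == "-", NA_integer_, s0 + cumsum(sub != "-"))
  both <- !is.na(tpos) & !is.na(spos)
  matches <- both & pat == sub
  mism <- both & pat != sub
  aligned_cols <- sum(both)
  mismatches <- tibble(
    target_pos = tpos[mism],
    target_res = pat[mism],
    template_res = sub[mism]
  )
  structure(list(
    identity = round(100 * sum(matches) / aligned_cols, 2),
    coverage = round(100 * sum(both) / nchar(target), 2),
    n_matches = sum(matches),
    n_mismatches = sum(mism),
    mismatches = mismatches,
    aligned = tibble(target_pos = tpos, template_pos = spos,
                     target_res = pat, template_res = sub),
    score = Biostrings::score(aln)
  ), class = "alignment_result")
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> identity %.2f%%, coverage %.2f%%, %d mismatch(es)\n",
              x$identity, x$coverage, x$n_mismatches))
  invisible(x)
}

#' Backbone phi/psi dihedrals
#'
#' Computes the standard backbone dihedrals from consecutive-residue
#' N/CA/C quadruples: phi(i) from C(i-1), N(i), CA(i), C(i) and psi(i)
#' from N(i), CA(i), C(i), N(i+1). Chain continuity requires consecutive
#' CA atoms within 4.5 Angstrom; a break terminates angle chaining, so the
#' flanking residues are treated as termini (phi of the first and psi of
#' the last residue of each stretch are `NA`). Residues missing a backbone
#' atom are skipped with a message.
#'
#' @param structure A path to a PDB file, or a data frame with columns
#'   `name` (atom name), `resid`, `resname`, `x`, `y`, `z`.
#' @return A tibble: `resid`, `resname`, `phi`, `psi` (degrees in
#'   (-180, 180]).
#' @export
phi_psi <- function(structure) {
  at <- backbone_table(structure)
  resids <- unique(at$resid)
  get_atom <- function(resid, name) {
    r <- at[at$resid == resid & at$name == name, , drop = FALSE]
    if (nrow(r) != 1) return(NULL)
    c(r$x, r$y, r$z)
  }
  bb <- lapply(resids, function(r) {
    list(N = get_atom(r, "N"), CA = get_atom(r, "CA"), C = get_atom(r, "C"))
  })
  ok <- vapply(bb, function(b) !any(vapply(b, is.null, logical(1))), logical(1))
  if (any(!ok)) {
    message("skipping residue(s) with missing backbone atoms: ",
            paste(resids[!ok], collapse = ", "))
  }
  resids <- resids[ok]; bb <- bb[ok]
  n <- length(resids)
  resname <- vapply(resids, function(r) at$resname[at$resid == r][1], character(1))
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  if (n >= 2) {
    linked <- vapply(seq_len(n - 1), function(i) {
      sqrt(sum((bb[[i + 1]]$CA - bb[[i]]$CA)^2)) <= 4.5
    }, logical(1))
    for (i in seq_len(n)) {
      if (i > 1 && linked[i - 1]) {
        phi[i] <- dihedral_angle(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      }
      if (i < n && linked[i]) {
        psi[i] <- dihedral_angle(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
      }
    }
  }
  tibble(resid = resids, resname = resname, phi = phi, psi = psi)
}

backbone_table <- function(structure) {
  if (is.character(structure) && length(structure) == 1) {
    pdb <- bio3d::read.pdb(structure, verbose = FALSE)
    tibble(name = trimws(pdb$atom$elety), resid = as.integer(pdb$atom$resno),
           resname = pdb$atom$resid, x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z)
  } else {
    at <- as_tibble(structure)
    need <- c("name", "resid", "resname", "x", "y", "z")
    if (!all(need %in% names(at))) {
      abort(paste0("structure table needs columns: ", paste(need, collapse = ", ")))
    }
    at
  }
}

#' Dihedral angle of four points
#'
#' Signed torsion angle in degrees in (-180, 180], by the standard
#' atan2 formulation on the two plane normals.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

#' Load the bundled coarse Ramachandran region map
#'
#' @param path Optional custom JSON region file.
#' @return A list with class `rama_map` holding `favored` and `allowed`
#'   polygon lists.
#' @export
load_rama_map <- function(path = NULL) {
  path <- path %||% extdata_path("rama_regions.json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(favored = obj$favored, allowed = obj$allowed,
                 version = obj$version %||% "unversioned"),
            class = "rama_map")
}

in_any_polygon <- function(phi, psi, polys) {
  if (is.data.frame(polys)) polys <- split(polys, seq_len(nrow(polys)))
  for (p in polys) {
    phis <- unlist(p$phi); psis <- unlist(p$psi)
    # inpolygon with boundary points counted as inside
    if (pracma::inpolygon(phi, psi, phis, psis, boundary = TRUE)) return(TRUE)
  }
  FALSE
}

#' Ramachandran classification
#'
#' Assigns each residue with both dihedrals to exactly one of
#' `favored`, `allowed`, `outlier` using the (coarse) bundled polygon map.
#' Points on a polygon edge take the more favorable class. Percentages are
#' over classifiable residues (those with both angles).
#'
#' @param records A [phi_psi()] tibble.
#' @param region_map An [load_rama_map()] result.
#' @return A list with class `rama_result`: `labels` (the input tibble plus
#'   a `label` column), `counts` (named integer vector) and `percent`
#'   (named numeric vector).
#' @export
rama_classify <- function(records, region_map = load_rama_map()) {
  records <- as_tibble(records)
  lab <- rep(NA_character_, nrow(records))
  classifiable <- which(is.finite(records$phi) & is.finite(records$psi))
  for (i in classifiable) {
    lab[i] <- if (in_any_polygon(records$phi[i], records$psi[i], region_map$favored)) {
      "favored"
    } else if (in_any_polygon(records$phi[i], records$psi[i], region_map$allowed)) {
      "allowed"
    } else {
      "outlier"
    }
  }
  counts <- c(
    favored = sum(lab == "favored", na.rm = TRUE),
    allowed = sum(lab == "allowed", na.rm = TRUE),
    outlier = sum(lab == "outlier", na.rm = TRUE)
  )
  total <- length(classifiable)
  percent <- if (total) round(100 * counts / total, 2) else counts * 0
  records$label <- lab
  structure(list(labels = records, counts = counts, percent = percent),
            class = "rama_result")
}
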