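#' Molecular graphs and conformers
#'
#' `molecule_graph()` builds the light-weight molecule container used across
#' the package: an atom table (element, formal charge), a bond table
#' (1-based atom indices `i`, `j` and order, where order 4 denotes an
#' aromatic bond as in SDF V2000), and optional 3D coordinates in Angstrom.
#' `conformer()` pairs a molecule with a complete coordinate set.
#'
#' @param atoms A data frame with columns `element` (chemical symbol) and
#'   optionally `charge` (integer formal charge, default 0).
#' @param bonds A data frame with columns `i`, `j` (atom indices) and
#'   `order` (1, 2, 3 or 4 for aromatic). May have zero rows.
#' @param coords Optional numeric matrix with one row per atom and columns
#'   x, y, z (Angstrom).
#' @param name Optional molecule name.
#' @return An object of class `molecule_graph`.
#' @examples
#' water <- molecule_graph(data.frame(element = "O"), data.frame(i = integer(), j = integer(), order = integer()))
#' mol_formula(water)
#' @export
molecule_graph <- function(atoms, bonds, coords = NULL, name = NULL) {
  atoms <- as_tibble(atoms)
  if (!"element" %in% names(atoms)) abort("`atoms` needs an `element` column")
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  bonds <- as_tibble(bonds)
  for (col in c("i", "j", "order")) {
    if (!col %in% names(bonds)) abort(paste0("`bonds` needs an `", col, "` column"))
  }
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      abort("bond endpoints must index valid atoms")
    }
    if (any(bonds$i == bonds$j)) abort("self-bonds are not allowed")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      abort("`coords` must be an N x 3 matrix covering all atoms")
    }
    if (!all(is.finite(coords))) abort("coordinates must be finite")
    dimnames(coords) <- NULL
  }
  structure(
    list(atoms = atoms, bonds = bonds, coords = coords, name = name),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  atoms:", nrow(x$atoms), " bonds:", nrow(x$bonds),
      " coords:", if (is.null(x$coords)) "none" else "3D", "\n")
  cat("  formula:", mol_formula(x), "\n")
  invisible(x)
}

#' @rdname molecule_graph
#' @param mol A `molecule_graph`.
#' @export
conformer <- function(mol, coords = NULL) {
  stopifnot(inherits(mol, "molecule_graph"))
  coords <- coords %||% mol$coords
  if (is.null(coords)) abort("a conformer needs 3D coordinates")
  mol <- molecule_graph(mol$atoms, mol$bonds, coords, mol$name)
  class(mol) <- c("conformer", "molecule_graph")
  mol
}

n_atoms <- function(mol) nrow(mol$atoms)

# Standard atomic weights (IUPAC 2021, conventional values) for the elements
# screening libraries actually contain.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

# Default valences used to infer implicit hydrogen counts on heavy atoms.
DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  deg <- integer(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      s[i] <- s[i] + ord[k]; s[j] <- s[j] + ord[k]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
  }
  list(order_sum = s, degree = deg)
}

#' Implicit hydrogen counts
#'
#' Infers implicit hydrogens from default valences, formal charge and the
#' sum of bond orders (aromatic bonds count 1.5). Atoms already carrying
#' explicit hydrogens get no extras because those bonds consume valence.
#'
#' @param mol A `molecule_graph`.
#' @return Integer vector, one entry per atom.
#' @export
implicit_h <- function(mol) {
  bs <- bond_order_sum(mol)
  el <- mol$atoms$element
  val <- unname(DEFAULT_VALENCE[el])
  # charge corrections for the common organic cases: N+ gains a bond,
  # O-/N-/S- lose one
  val <- val + ifelse(el %in% c("N", "P") & mol$atoms$charge > 0, mol$atoms$charge, 0)
  val <- val + ifelse(mol$atoms$charge < 0, mol$atoms$charge, 0)
  h <- val - bs$order_sum
  h[is.na(h)] <- 0          # metals / unknown valence: assume none
  as.integer(pmax(0, round(h)))
}

# Total attached hydrogens (explicit neighbours + implicit).
total_h <- function(mol) {
  n <- n_atoms(mol)
  expl <- integer(n)
  if (nrow(mol$bonds)) {
    isH <- mol$atoms$element == "H"
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (isH[j]) expl[i] <- expl[i] + 1L
      if (isH[i]) expl[j] <- expl[j] + 1L
    }
  }
  expl + implicit_h(mol)
}

#' Molecular formula and weight
#'
#' @param mol A `molecule_graph`.
#' @return `mol_formula()` a Hill-order formula string; `mol_weight()` the
#'   molecular weight in g/mol including implicit hydrogens.
#' @export
mol_formula <- function(mol) {
  el <- mol$atoms$element
  counts <- table(el)
  nh <- sum(implicit_h(mol)) + sum(el == "H")
  counts <- counts[names(counts) != "H"]
  ord <- c(intersect(c("C"), names(counts)),
           sort(setdiff(names(counts), "C")))
  parts <- vapply(ord, function(e) {
    paste0(e, if (counts[[e]] > 1) counts[[e]] else "")
  }, character(1))
  if (nh > 0) {
    hpart <- paste0("H", if (nh > 1) nh else "")
    if ("C" %in% ord) {
      parts <- append(parts, hpart, after = 1)
    } else {
      parts <- sort(c(parts, hpart))
    }
  }
  paste(parts, collapse = "")
}

#' @rdname mol_formula
#' @export
mol_weight <- function(mol) {
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), names(ATOMIC_WEIGHTS))
  if (length(unknown)) {
    abort(paste0("no tabulated atomic weight for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sum(ATOMIC_WEIGHTS[el]) + sum(implicit_h(mol)) * ATOMIC_WEIGHTS[["H"]]
}

# ---- ring perception -------------------------------------------------------

mol_igraph <- function(mol, heavy_only = FALSE) {
  keep <- if (heavy_only) which(mol$atoms$element != "H") else seq_len(n_atoms(mol))
  idx <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(b)) {
    g <- igraph::add_edges(g, rbind(idx[b$i], idx[b$j]))
    igraph::E(g)$order <- b$order
  }
  igraph::V(g)$element <- mol$atoms$element[keep]
  igraph::V(g)$charge <- mol$atoms$charge[keep]
  igraph::V(g)$orig <- keep
  g
}

# Smallest ring through each bond (sizes <= max_size), deduplicated.
find_rings <- function(mol, max_size = 8) {
  g <- mol_igraph(mol, heavy_only = TRUE)
  orig <- igraph::V(g)$orig
  rings <- list()
  seen <- character()
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(rings)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1]; b <- el[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = a, to = b)$vpath[[1]])
    if (length(sp) > 1 && length(sp) <= max_size) {
      ring <- orig[as.integer(sp)]
      key <- paste(sort(ring), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- ring
      }
    }
  }
  rings
}

# Aromaticity: a ring is aromatic when every ring bond is marked aromatic
# (order 4), or -- for kekulized input -- when the ring has 5 or 6 members,
# only C/N/O/S atoms, and every ring atom either takes part in a double bond
# to another ring atom or is a heteroatom contributing a lone pair. This
# covers benzene, pyridine, furan, pyrrole, thiophene and azoles; it is a
# deliberate simplification, not a Hueckel electron count.
aromatic_rings <- function(mol) {
  rings <- find_rings(mol, max_size = 7)
  keep(rings, function(r) ring_is_aromatic(mol, r))
}

ring_is_aromatic <- function(mol, ring) {
  b <- mol$bonds
  inring <- function(i, j) {
    pos_i <- match(i, ring); pos_j <- match(j, ring)
    if (is.na(pos_i) || is.na(pos_j)) return(FALSE)
    k <- length(ring)
    abs(pos_i - pos_j) == 1 || abs(pos_i - pos_j) == k - 1
  }
  ring_bonds <- b[mapply(inring, b$i, b$j), , drop = FALSE]
  if (nrow(ring_bonds) != length(ring)) return(FALSE)
  if (all(ring_bonds$order == 4)) return(TRUE)
  if (!length(ring) %in% c(5L, 6L)) return(FALSE)
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  ok <- vapply(ring, function(a) {
    dbl <- ring_bonds$order == 2 & (ring_bonds$i == a | ring_bonds$j == a)
    any(dbl) || mol$atoms$element[a] %in% c("N", "O", "S")
  }, logical(1))
  all(ok)
}

# Atoms belonging to at least one aromatic ring.
aromatic_atoms <- function(mol) {
  sort(unique(unlist(aromatic_rings(mol))))
}

neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}
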