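#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of point set `B` onto `A`
#' (row-per-point matrices) via singular value decomposition, constrained
#' to a proper rotation (det = +1).
#'
#' @param A,B N x 3 coordinate matrices (N >= 3) of paired points.
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   aligned coordinates are `B %*% rotation` + translation), `rmsd`
#'   (Angstrom) and `aligned` (the transformed `B`).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) abort("point sets must have matching dimensions")
  if (nrow(A) < 3) abort("superposition needs at least 3 points")
  cA <- colMeans(A); cB <- colMeans(B)
  P <- sweep(B, 2, cB); Q <- sweep(A, 2, cA)
  M <- crossprod(P, Q)          # t(P) %*% Q
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((Q - aligned)^2)))
  aligned <- sweep(aligned, 2, cA, "+")
  list(rotation = R, translation = cA - as.numeric(cB %*% R), rmsd = rmsd,
       aligned = aligned)
}

# plain coordinate RMSD with identity pairing
coord_rmsd <- function(A, B) {
  sqrt(mean(rowSums((A - B)^2)))
}

#' Graph automorphisms of a molecule
#'
#' Enumerates all element- and bond-order-preserving atom permutations of
#' a (connected) molecular graph by backtracking with element/degree/
#' neighborhood pruning. The identity is always included. Searching is
#' capped: highly symmetric molecules exceeding `cap` mappings raise an
#' error advising symmetry reduction.
#'
#' @param mol A [molecule_graph()].
#' @param heavy_only Drop hydrogens before enumeration (default `TRUE`).
#' @param cap Maximum number of mappings to enumerate (default 10000).
#' @return A list of integer permutation vectors.
#' @export
automorphisms <- function(mol, heavy_only = TRUE, cap = 10000L) {
  g <- subgraph_spec(mol, heavy_only)
  maps <- find_isomorphisms(g, g, cap = cap)
  if (is.null(maps)) {
    abort(paste0("more than ", cap, " automorphisms; reduce symmetry or raise the cap"))
  }
  maps
}

# internal compact graph representation for isomorphism search
subgraph_spec <- function(mol, heavy_only = TRUE) {
  keep <- if (heavy_only) which(mol$atoms$element != "H") else seq_len(n_atoms(mol))
  idx <- match(seq_len(n_atoms(mol)), keep)
  n <- length(keep)
  adj <- matrix(0L, n, n)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  if (nrow(b)) {
    ii <- idx[b$i]; jj <- idx[b$j]
    adj[cbind(ii, jj)] <- as.integer(b$order)
    adj[cbind(jj, ii)] <- as.integer(b$order)
  }
  list(n = n, el = mol$atoms$element[keep], adj = adj, orig = keep)
}

# All isomorphisms g1 -> g2 preserving element labels and bond orders.
# Returns NULL when `cap` is exceeded.
find_isomorphisms <- function(g1, g2, cap = 10000L) {
  if (g1$n != g2$n) return(list())
  deg1 <- rowSums(g1$adj > 0); deg2 <- rowSums(g2$adj > 0)
  sig <- function(g, deg) {
    vapply(seq_len(g$n), function(i) {
      nb <- which(g$adj[i, ] > 0)
      paste(g$el[i], deg[i],
            paste(sort(paste0(g$el[nb], ":", g$adj[i, nb])), collapse = ","),
            sep = "|")
    }, character(1))
  }
  s1 <- sig(g1, deg1); s2 <- sig(g2, deg2)
  cands <- lapply(seq_len(g1$n), function(i) which(s2 == s1[i]))
  if (any(!lengths(cands))) return(list())
  ord <- order(lengths(cands))
  maps <- list()
  overflow <- FALSE
  assign_next <- function(level, mapping) {
    if (overflow) return(invisible())
    if (level > g1$n) {
      if (length(maps) >= cap) { overflow <<- TRUE; return(invisible()) }
      maps[[length(maps) + 1L]] <<- mapping
      return(invisible())
    }
    v <- ord[level]
    for (w in cands[[v]]) {
      if (w %in% mapping) next
      ok <- TRUE
      if (level > 1) {
        for (lv in seq_len(level - 1)) {
          u <- ord[lv]
          if (g1$adj[v, u] != g2$adj[w, mapping[u]]) { ok <- FALSE; break }
        }
      }
      if (ok) {
        mp <- mapping; mp[v] <- w
        assign_next(level + 1L, mp)
      }
    }
  }
  assign_next(1L, rep(NA_integer_, g1$n))
  if (overflow) NULL else maps
}

#' Symmetry-corrected pose RMSD
#'
#' RMSD between two poses of the same ligand, minimized over all graph
#' isomorphisms between the two heavy-atom molecular graphs (so chemically
#' equivalent atoms -- e.g. the two ortho carbons of a phenyl ring -- never
#' inflate the deviation). `superpose = FALSE` (the docking-community
#' convention) compares coordinates in place; `superpose = TRUE` first
#' Kabsch-aligns the probe onto the reference for every candidate mapping.
#'
#' @param ref,probe [conformer()]s of the same molecule.
#' @param superpose Align before measuring (default `FALSE`).
#' @param heavy_only Use heavy atoms only (default `TRUE`).
#' @param cap Mapping cap, as in [automorphisms()].
#' @return A list with class `pose_rmsd`: `value` (Angstrom), `mapping`
#'   (the minimizing atom permutation, ref index -> probe index, over the
#'   atoms used) and `superposed`.
#' @export
symmetry_rmsd <- function(ref, probe, superpose = FALSE, heavy_only = TRUE,
                          cap = 10000L) {
  stopifnot(inherits(ref, "molecule_graph"), inherits(probe, "molecule_graph"))
  if (is.null(ref$coords) || is.null(probe$coords)) {
    abort("both poses need 3D coordinates")
  }
  g1 <- subgraph_spec(ref, heavy_only)
  g2 <- subgraph_spec(probe, heavy_only)
  maps <- find_isomorphisms(g1, g2, cap = cap)
  if (is.null(maps)) {
    abort(paste0("more than ", cap, " candidate mappings; reduce symmetry or raise the cap"))
  }
  if (!length(maps)) abort("poses are not graph-isomorphic; not the same ligand")
  A <- ref$coords[g1$orig, , drop = FALSE]
  Bfull <- probe$coords[g2$orig, , drop = FALSE]
  best <- NULL; best_val <- Inf
  for (mp in maps) {
    B <- Bfull[mp, , drop = FALSE]
    val <- if (superpose) kabsch_superpose(A, B)$rmsd else coord_rmsd(A, B)
    if (val < best_val) { best_val <- val; best <- mp }
  }
  structure(list(value = best_val, mapping = best, superposed = superpose),
            class = "pose_rmsd")
}

#' @export
print.pose_rmsd <- function(x, ...) {
  cat("<pose_rmsd> ", format(x$value, digits = 6), " A (",
      if (x$superposed) "superposed" else "in place", ")\n", sep = "")
  invisible(x)
}
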