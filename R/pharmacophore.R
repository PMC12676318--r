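#' Pharmacophore features and models
#'
#' A pharmacophore model is a tibble of typed feature spheres: columns
#' `index`, `kind` (one of `acceptor`, `donor`, `hydrophobic`, `aromatic`),
#' `x`, `y`, `z` (Angstrom) and `radius`.
#'
#' @param features A data frame with those columns.
#' @param name Model name.
#' @return A tibble with class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, name = "model") {
  features <- as_tibble(features)
  need <- c("index", "kind", "x", "y", "z", "radius")
  if (!all(need %in% names(features))) {
    abort(paste0("features need columns: ", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(features$kind), FEATURE_KINDS)
  if (length(bad)) abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
  if (any(features$radius <= 0)) abort("feature radii must be positive")
  if (!all(is.finite(as.matrix(features[c("x", "y", "z")])))) {
    abort("feature centers must be finite")
  }
  structure(features, class = c("pharmacophore_model", class(features)),
            model_name = name)
}

FEATURE_KINDS <- c("acceptor", "donor", "hydrophobic", "aromatic")

feature_coords <- function(features) {
  unname(as.matrix(features[, c("x", "y", "z")]))
}

#' Perceive pharmacophore features on a 3D conformer
#'
#' Detection rules: donors are N/O atoms bearing at least one hydrogen;
#' acceptors are all O atoms plus N atoms with a free lone pair (no
#' hydrogen, at most three connections, no positive charge -- this excludes
#' pyrrole-type nitrogens); aromatic features sit at aromatic-ring
#' centroids; hydrophobic features sit at aromatic-ring centroids, at
#' sulfur atoms bonded only to carbon, and at terminal aliphatic carbons
#' not bonded to oxygen or to charged atoms.
#'
#' @param conf A [conformer()] (or `molecule_graph` with 3D coordinates).
#' @param radius Feature sphere radius assigned to every perceived feature.
#' @return A tibble of features (`kind`, `x`, `y`, `z`, `radius`, `atoms`
#'   list-column of supporting atom indices).
#' @export
perceive_features <- function(conf, radius = 1.0) {
  stopifnot(inherits(conf, "molecule_graph"))
  if (is.null(conf$coords)) abort("feature perception needs 3D coordinates")
  co <- conf$coords
  el <- conf$atoms$element
  chg <- conf$atoms$charge
  hs <- total_h(conf)
  arom <- aromatic_rings(conf)
  arom_atoms <- sort(unique(unlist(arom)))
  heavy_deg <- vapply(seq_len(n_atoms(conf)), function(i) {
    sum(el[neighbors_of(conf, i)] != "H")
  }, integer(1))

  feats <- list()
  add <- function(kind, center, atoms) {
    feats[[length(feats) + 1L]] <<- tibble(
      kind = kind, x = center[1], y = center[2], z = center[3],
      radius = radius, atoms = list(atoms)
    )
  }

  for (i in which(el %in% c("N", "O"))) {
    if (hs[i] > 0) add("donor", co[i, ], i)
    is_acceptor <- if (el[i] == "O") {
      chg[i] <= 0
    } else {
      hs[i] == 0 && chg[i] <= 0 && (heavy_deg[i] + hs[i]) <= 3
    }
    if (is_acceptor) add("acceptor", co[i, ], i)
  }
  for (ring in arom) {
    cen <- colMeans(co[ring, , drop = FALSE])
    add("aromatic", cen, ring)
    add("hydrophobic", cen, ring)
  }
  for (i in which(el == "S")) {
    nb <- neighbors_of(conf, i)
    nb <- nb[el[nb] != "H"]
    if (length(nb) && all(el[nb] == "C")) add("hydrophobic", co[i, ], i)
  }
  for (i in which(el == "C")) {
    if (heavy_deg[i] != 1L || i %in% arom_atoms) next
    nb <- neighbors_of(conf, i)
    nb <- nb[el[nb] != "H"]
    if (any(el[nb] == "O") || any(chg[nb] != 0)) next
    add("hydrophobic", co[i, ], i)
  }
  if (!length(feats)) {
    return(tibble(kind = character(), x = numeric(), y = numeric(),
                  z = numeric(), radius = numeric(), atoms = list()))
  }
  bind_rows(feats)
}

#' Build the reference agonist pharmacophore model
#'
#' Derives the eight-feature thiazolidinedione-agonist model from a 3D
#' rosiglitazone-like conformer: (1) acceptor on the ring amide oxygen,
#' (2) donor on the ring amide N-H, (3) hydrophobic on the thioether
#' sulfur, (4) aromatic and (5) hydrophobic on the disubstituted benzene
#' centroid, (6) hydrophobic and (7) aromatic on the pyridine centroid,
#' and (8) hydrophobic on the tertiary-amine methyl carbon.
#'
#' @param rgz_conformer A 3D conformer of rosiglitazone (see the bundled
#'   `rgz_synthetic.sdf`).
#' @param radius Feature sphere radius (Angstrom).
#' @return A [pharmacophore_model()] with 8 features.
#' @export
build_reference_model <- function(rgz_conformer, radius = 1.0) {
  conf <- rgz_conformer
  stopifnot(inherits(conf, "molecule_graph"))
  if (is.null(conf$coords)) abort("reference conformer needs 3D coordinates")
  co <- conf$coords
  el <- conf$atoms$element
  hs <- total_h(conf)
  fail <- function(k, what) {
    abort(paste0("cannot place feature ", k, ": ", what, " not found"))
  }

  s_idx <- which(el == "S")
  if (!length(s_idx)) fail(3, "sulfur atom")
  s_idx <- s_idx[1]

  # ring amide: N bearing H bonded to a carbonyl carbon; the acceptor is the
  # carbonyl O on the amide carbon not bonded to sulfur
  amide_n <- NULL; amide_o <- NULL
  for (n in which(el == "N" & hs > 0)) {
    for (c_at in neighbors_of(conf, n)) {
      if (el[c_at] != "C") next
      dbl_o <- conf$bonds$order == 2 &
        ((conf$bonds$i == c_at & el[conf$bonds$j] == "O") |
         (conf$bonds$j == c_at & el[conf$bonds$i] == "O"))
      if (!any(dbl_o)) next
      if (s_idx %in% neighbors_of(conf, c_at)) next   # prefer the pure amide
      k <- which(dbl_o)[1]
      amide_o <- if (el[conf$bonds$i[k]] == "O") conf$bonds$i[k] else conf$bonds$j[k]
      amide_n <- n
    }
  }
  if (is.null(amide_n)) fail(2, "amide N-H")
  if (is.null(amide_o)) fail(1, "amide carbonyl oxygen")

  rings <- aromatic_rings(conf)
  benzene <- keep(rings, function(r) all(el[r] == "C") && length(r) == 6)
  if (!length(benzene)) fail(4, "all-carbon aromatic ring")
  pyridine <- keep(rings, function(r) sum(el[r] == "N") == 1 && length(r) == 6)
  if (!length(pyridine)) fail(6, "pyridine ring")
  benzene_cen <- colMeans(co[benzene[[1]], , drop = FALSE])
  pyridine_cen <- colMeans(co[pyridine[[1]], , drop = FALSE])

  # tertiary-amine methyl: terminal carbon on an N with three heavy
  # neighbours and no hydrogen
  methyl <- NULL
  for (n in which(el == "N" & hs == 0)) {
    nb <- neighbors_of(conf, n)
    nb <- nb[el[nb] != "H"]
    if (length(nb) != 3) next
    for (c_at in nb[el[nb] == "C"]) {
      cnb <- neighbors_of(conf, c_at)
      if (sum(el[cnb] != "H") == 1L) methyl <- c_at
    }
  }
  if (is.null(methyl)) fail(8, "tertiary-amine methyl carbon")

  centers <- rbind(
    co[amide_o, ], co[amide_n, ], co[s_idx, ],
    benzene_cen, benzene_cen, pyridine_cen, pyridine_cen, co[methyl, ]
  )
  dimnames(centers) <- NULL
  pharmacophore_model(
    tibble(
      index = 1:8,
      kind = c("acceptor", "donor", "hydrophobic", "aromatic",
               "hydrophobic", "hydrophobic", "aromatic", "hydrophobic"),
      x = centers[, 1], y = centers[, 2], z = centers[, 3],
      radius = radius
    ),
    name = "tzd_agonist_8feat"
  )
}

#' Match a pharmacophore model against a conformer
#'
#' Alignment-free matching by pairwise-distance consistency: searches for
#' an injective, kind-respecting assignment of model features to perceived
#' features such that every model feature-pair distance is reproduced
#' within the tolerance (a clique in the correspondence graph). Among all
#' feasible assignments the one minimizing the maximum pairwise deviation
#' is returned; exact ties resolve to the lexicographically smallest
#' mapping. Being built on pairwise distances only, the result is invariant
#' under rigid motion and atom relabeling of the conformer.
#'
#' @param model A [pharmacophore_model()].
#' @param conf A [conformer()] with 3D coordinates.
#' @param tol Distance-deviation tolerance per feature pair (Angstrom).
#' @param use_radii If `TRUE`, each pair's tolerance is
#'   `max(radius_i, radius_j)` of the model features instead of `tol`.
#' @return A list with class `pharm_match`: `matched` (logical), `mapping`
#'   (integer vector, model feature index -> perceived feature row; `NA`
#'   when unmatched) and `max_deviation` (Angstrom; `Inf` when unmatched).
#' @export
match_pharmacophore <- function(model, conf, tol = 1.0, use_radii = FALSE) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (!use_radii) assert_scalar_finite(tol, "tol")
  if (!use_radii && tol <= 0) abort("`tol` must be positive")
  perceived <- perceive_features(conf)
  m <- nrow(model)
  mc <- feature_coords(model)
  dm <- as.matrix(stats::dist(mc))
  pair_tol <- matrix(tol, m, m)
  if (use_radii) {
    pair_tol <- outer(model$radius, model$radius, pmax)
  }
  if (!nrow(perceived)) {
    return(structure(list(matched = FALSE, mapping = rep(NA_integer_, m),
                          max_deviation = Inf), class = "pharm_match"))
  }
  pc <- feature_coords(perceived)
  dp <- as.matrix(stats::dist(pc))
  cands <- lapply(model$kind, function(k) which(perceived$kind == k))

  best <- list(mapping = NULL, max_dev = Inf)
  assign_next <- function(level, mapping, cur_max) {
    if (level > m) {
      if (cur_max < best$max_dev) best <<- list(mapping = mapping, max_dev = cur_max)
      return(invisible())
    }
    for (cand in cands[[level]]) {
      if (cand %in% mapping) next
      new_max <- cur_max
      ok <- TRUE
      if (level > 1) {
        for (prev in seq_len(level - 1)) {
          dev <- abs(dm[level, prev] - dp[cand, mapping[prev]])
          if (dev > pair_tol[level, prev]) { ok <- FALSE; break }
          if (dev > new_max) new_max <- dev
        }
      }
      if (ok && new_max < best$max_dev) {
        assign_next(level + 1, c(mapping, cand), new_max)
      }
    }
  }
  assign_next(1L, integer(0), 0)
  if (is.null(best$mapping)) {
    structure(list(matched = FALSE, mapping = rep(NA_integer_, m),
                   max_deviation = Inf), class = "pharm_match")
  } else {
    structure(list(matched = TRUE, mapping = best$mapping,
                   max_deviation = best$max_dev), class = "pharm_match")
  }
}

#' @export
print.pharm_match <- function(x, ...) {
  if (x$matched) {
    cat("<pharm_match> matched, max deviation", format(x$max_deviation, digits = 4), "A\n")
  } else {
    cat("<pharm_match> no feasible assignment\n")
  }
  invisible(x)
}

#' Read/write pharmacophore models as JSON
#'
#' @param model A [pharmacophore_model()].
#' @param path JSON file path.
#' @return `read_pharmacophore()` returns a model; `write_pharmacophore()`
#'   the path, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  jsonlite::write_json(
    list(name = attr(model, "model_name"),
         features = as.data.frame(model[, c("index", "kind", "x", "y", "z", "radius")])),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pharmacophore_model(as_tibble(obj$features), name = obj$name %||% "model")
}
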