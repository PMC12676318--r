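#' Quadrant filter against a reference ligand
#'
#' Keeps candidates at least as good as the reference on both axes:
#' docking affinity less than or equal to (at least as favorable as) the
#' reference's, and predicted LD50 greater than or equal to (at least as
#' safe as) the reference's. Both thresholds are inclusive, so a candidate
#' tying the reference on one axis still passes. Input order is preserved
#' and the reference itself is excluded from the candidates.
#'
#' @param records A compound tibble with `affinity_kcal_mol` and
#'   `ld50_mol_kg` columns.
#' @param reference A one-row data frame or list with `id` (optional),
#'   `affinity_kcal_mol` and `ld50_mol_kg`.
#' @return The subset of `records` inside the quadrant.
#' @export
quadrant_filter <- function(records, reference) {
  records <- as_tibble(records)
  ref_aff <- as.numeric(reference$affinity_kcal_mol[1])
  ref_ld50 <- as.numeric(reference$ld50_mol_kg[1])
  assert_scalar_finite(ref_aff, "reference$affinity_kcal_mol")
  assert_scalar_finite(ref_ld50, "reference$ld50_mol_kg")
  ref_id <- if (!is.null(reference$id)) as.character(reference$id[1]) else NULL
  if (!is.null(ref_id)) records <- records[records$id != ref_id, , drop = FALSE]
  bad <- records$id[!is.finite(records$affinity_kcal_mol) |
                    !is.finite(records$ld50_mol_kg)]
  if (length(bad)) {
    abort(paste0("candidate(s) missing affinity or ld50: ",
                 paste(bad, collapse = ", ")))
  }
  records[records$affinity_kcal_mol <= ref_aff &
          records$ld50_mol_kg >= ref_ld50, , drop = FALSE]
}

#' Ideal point for multi-objective ranking
#'
#' The hypothetical best compound in (affinity, LD50) space: the most
#' favorable (most negative) affinity and the largest LD50. Supply both
#' values explicitly to pin the point (e.g. when the extremes come from a
#' larger set than the one being ranked), or pass `records` to take the
#' componentwise extremes of the set.
#'
#' @param records Optional compound tibble (from-set mode).
#' @param affinity_min,ld50_max Explicit coordinates (explicit mode).
#' @return A list with class `ideal_point`: `affinity_min`, `ld50_max`,
#'   `provenance` (`"explicit"` or `"from_set"`).
#' @export
ideal_point <- function(records = NULL, affinity_min = NULL, ld50_max = NULL) {
  if (!is.null(affinity_min) && !is.null(ld50_max)) {
    assert_scalar_finite(affinity_min, "affinity_min")
    assert_scalar_finite(ld50_max, "ld50_max")
    return(structure(list(affinity_min = affinity_min, ld50_max = ld50_max,
                          provenance = "explicit"), class = "ideal_point"))
  }
  if (is.null(records) || !nrow(records)) {
    abort("from-set ideal point needs a non-empty record set")
  }
  structure(list(
    affinity_min = min(records$affinity_kcal_mol),
    ld50_max = max(records$ld50_mol_kg),
    provenance = "from_set"
  ), class = "ideal_point")
}

#' @export
print.ideal_point <- function(x, ...) {
  cat("<ideal_point> affinity_min =", x$affinity_min, "kcal/mol, ld50_max =",
      x$ld50_max, "mol/kg (", x$provenance, ")\n")
  invisible(x)
}

#' Ideal-point Euclidean ranking
#'
#' Ranks compounds by their Euclidean distance to the ideal point,
#' `dist_i = sqrt((affinity_i - affinity_min)^2 + (ld50_i - ld50_max)^2)`,
#' computed directly on the printed units (kcal/mol and mol/kg mixed with
#' no rescaling -- the convention of the source ranking). The optional
#' `normalize` mode z-scores both axes (and transforms the ideal point
#' accordingly) before measuring, as a unit-hygiene alternative; it is off
#' by default so published rankings reproduce exactly. Ties in distance
#' break lexicographically by id.
#'
#' @param records A compound tibble.
#' @param ideal An [ideal_point()].
#' @param normalize Z-score both axes first (default `FALSE`).
#' @return The records with `distance` and `ranking` columns, sorted by
#'   rank; class `ranked_hits`.
#' @export
euclidean_rank <- function(records, ideal, normalize = FALSE) {
  records <- as_tibble(records)
  if (!nrow(records)) abort("cannot rank an empty record set")
  stopifnot(inherits(ideal, "ideal_point"))
  aff <- records$affinity_kcal_mol
  ld <- records$ld50_mol_kg
  a0 <- ideal$affinity_min; l0 <- ideal$ld50_max
  if (normalize) {
    ma <- mean(aff); sa <- sd(aff); ml <- mean(ld); sl <- sd(ld)
    if (sa == 0) sa <- 1
    if (sl == 0) sl <- 1
    a0 <- (a0 - ma) / sa; l0 <- (l0 - ml) / sl
    aff <- (aff - ma) / sa; ld <- (ld - ml) / sl
  }
  records$distance <- sqrt((aff - a0)^2 + (ld - l0)^2)
  out <- records[order(records$distance, records$id), , drop = FALSE]
  out$ranking <- seq_len(nrow(out))
  out <- out[, c("ranking", setdiff(names(out), "ranking"))]
  class(out) <- c("ranked_hits", class(out))
  attr(out, "ideal") <- ideal
  out
}

#' Load the BOILED-Egg classifier ellipses
#'
#' Two ellipses in (TPSA, WLOGP) space: the white region bounds predicted
#' passive gastrointestinal absorption (HIA) and the yolk bounds predicted
#' blood-brain-barrier penetration (BBB). Parameters ship with the package.
#'
#' @param path Optional path to a custom JSON parameter file.
#' @return A list with class `egg_model`.
#' @export
load_egg_model <- function(path = NULL) {
  path <- path %||% extdata_path("boiled_egg_ellipses.json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("white", "yolk")) {
    e <- obj[[nm]]
    if (is.null(e) || e$width_tpsa <= 0 || e$height_wlogp <= 0) {
      abort("egg model needs valid 'white' and 'yolk' ellipses")
    }
  }
  structure(obj[c("white", "yolk")], version = obj$version %||% "unversioned",
            class = "egg_model")
}

in_ellipse <- function(tpsa, wlogp, e) {
  th <- e$angle_deg * pi / 180
  dx <- tpsa - e$center_tpsa
  dy <- wlogp - e$center_wlogp
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (e$width_tpsa / 2))^2 + (v / (e$height_wlogp / 2))^2 <= 1
}

#' BOILED-Egg classification
#'
#' Classifies compounds in (WLOGP, TPSA) space: `BBB` inside the yolk
#' ellipse (which wins overlaps), else `HIA` inside the white ellipse,
#' else `Out`. Total: every point gets exactly one region.
#'
#' @param wlogp,tpsa Numeric vectors.
#' @param model An [load_egg_model()] result.
#' @return Character vector of `"HIA"`, `"BBB"`, `"Out"`.
#' @export
boiled_egg <- function(wlogp, tpsa, model = load_egg_model()) {
  stopifnot(inherits(model, "egg_model"))
  ifelse(in_ellipse(tpsa, wlogp, model$yolk), "BBB",
         ifelse(in_ellipse(tpsa, wlogp, model$white), "HIA", "Out"))
}

#' Annotate a compound table with BOILED-Egg regions
#'
#' @param records A compound tibble with `wlogp` and `tpsa` columns.
#' @param model An [load_egg_model()] result.
#' @return The records with a `region` column.
#' @export
classify_egg <- function(records, model = load_egg_model()) {
  records <- as_tibble(records)
  if (!all(c("wlogp", "tpsa") %in% names(records))) {
    abort("records need `wlogp` and `tpsa` columns for BOILED-Egg classification")
  }
  records$region <- boiled_egg(records$wlogp, records$tpsa, model)
  records
}

#' Run the full hit-triage funnel
#'
#' Wires the stages in pipeline order: deduplication, qualitative
#' drug-likeness gate (only when structures are available), quadrant
#' filter against the reference, ideal-point Euclidean ranking, and
#' BOILED-Egg / P-gp annotation. Region columns present in the input are
#' treated as annotations and kept unless `wlogp`/`tpsa` are available to
#' classify from; the two sources are never silently mixed.
#'
#' @param records Compound tibble (see [read_compound_table()]).
#' @param reference A one-row data frame or list with `id`,
#'   `affinity_kcal_mol`, `ld50_mol_kg` (the reference ligand).
#' @param ideal An [ideal_point()]; defaults to from-set over the
#'   quadrant-passing records.
#' @param structures Optional named list of [molecule_graph()]s keyed by
#'   compound id, enabling the qualitative gate.
#' @param pains,brenk Alert catalogs for the qualitative gate.
#' @param dedup_by Deduplication key, `"id"` or `"structure"`.
#' @param egg_model Classifier for region annotation when `wlogp`/`tpsa`
#'   columns are present.
#' @return A list with class `funnel_result`: `ranked` (a `ranked_hits`
#'   tibble) and `report` (stage counts and parameters).
#' @export
run_funnel <- function(records, reference, ideal = NULL, structures = NULL,
                       pains = NULL, brenk = NULL, dedup_by = "id",
                       egg_model = NULL) {
  records <- as_tibble(records)
  counts <- list(input = nrow(records))

  deduped <- deduplicate_hits(records, by = dedup_by)
  counts$deduplicated <- nrow(deduped)

  if (!is.null(structures)) {
    pains <- pains %||% load_alert_catalog("pains")
    brenk <- brenk %||% load_alert_catalog("brenk")
    passed <- vapply(deduped$id, function(id) {
      mol <- structures[[id]]
      if (is.null(mol)) return(TRUE)   # no structure: table-only record passes through
      qualitative_pass(mol, pains, brenk)$pass
    }, logical(1))
    deduped <- deduped[passed, , drop = FALSE]
  }
  counts$qualitative_pass <- nrow(deduped)

  quad <- quadrant_filter(deduped, reference)
  counts$quadrant <- nrow(quad)
  if (!nrow(quad)) {
    warn("no candidates remain after the quadrant filter")
    return(structure(list(
      ranked = quad,
      report = list(counts = counts, reference = reference, ideal = ideal)
    ), class = "funnel_result"))
  }
  ideal <- ideal %||% ideal_point(quad)
  ranked <- euclidean_rank(quad, ideal)

  if (all(c("wlogp", "tpsa") %in% names(ranked)) &&
      all(is.finite(ranked$wlogp)) && all(is.finite(ranked$tpsa))) {
    ranked <- classify_egg(ranked, egg_model %||% load_egg_model())
    region_source <- "computed"
  } else {
    region_source <- if ("region" %in% names(ranked)) "annotation" else "absent"
  }
  counts$ranked <- nrow(ranked)
  class(ranked) <- unique(c("ranked_hits", class(ranked)))

  structure(list(
    ranked = ranked,
    report = list(
      counts = counts,
      reference = as.list(reference)[c("id", "affinity_kcal_mol", "ld50_mol_kg")],
      ideal = unclass(ideal)[c("affinity_min", "ld50_max", "provenance")],
      region_source = region_source,
      catalogs = list(
        pains = if (!is.null(pains)) attr(pains, "catalog_version"),
        brenk = if (!is.null(brenk)) attr(brenk, "catalog_version")
      )
    )
  ), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("<funnel_result>\n  stage counts:",
      paste(names(x$report$counts), unlist(x$report$counts),
            sep = "=", collapse = " -> "), "\n")
  if (nrow(x$ranked)) {
    cat("  top hit:", x$ranked$id[1],
        sprintf("(distance %.3f)", x$ranked$distance[1]), "\n")
  }
  invisible(x)
}
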