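#' Canonical compound-table column aliases
#'
#' The canonical schema is `id, smiles, affinity_kcal_mol, ld50_mol_kg,
#' wlogp, tpsa, pgp, region` (plus `ranking` and `distance` on ranked
#' tables). Published tables name these columns freely, so the reader maps
#' common variants through this alias table; supply your own to extend it.
#'
#' @return A named character vector mapping lower-cased source column names
#'   to canonical names.
#' @export
compound_aliases <- function() {
  c(
    "id" = "id", "mcule" = "id", "compound" = "id", "name" = "id",
    "smiles" = "smiles",
    "affinity_kcal_mol" = "affinity_kcal_mol",
    "affinity" = "affinity_kcal_mol",
    "affinity (kcal/mol)" = "affinity_kcal_mol",
    "affinity_kcal/mol" = "affinity_kcal_mol",
    "ld50_mol_kg" = "ld50_mol_kg", "ld50" = "ld50_mol_kg",
    "ld50 (mol/kg)" = "ld50_mol_kg", "ld_50" = "ld50_mol_kg",
    "wlogp" = "wlogp", "tpsa" = "tpsa",
    "pgp" = "pgp", "p-gp substrate" = "pgp", "pgp_substrate" = "pgp",
    "region" = "region", "boiled-egg region" = "region",
    "boiled_egg_region" = "region",
    "ranking" = "ranking", "rank" = "ranking",
    "distance" = "distance", "dist" = "distance"
  )
}

#' Read a compound table
#'
#' Reads a CSV/TSV of screening hits into the canonical compound schema.
#' Numeric columns tolerate unicode minus variants (en-dash, em-dash, true
#' minus) as printed tables often carry them. P-gp flags accept `+`/`-` as
#' well as logical spellings; regions must be `HIA`, `BBB` or `Out`.
#'
#' @param path Path to a delimited file (delimiter sniffed from extension:
#'   `.tsv` is tab, otherwise comma).
#' @param aliases Column alias map, see [compound_aliases()].
#' @param reference_ids Character vector of ids to flag as reference
#'   compounds (column `is_reference`).
#' @return A tibble of compound records with one row per data row.
#' @examples
#' path <- system.file("extdata", "table3_hits.csv", package = "hitfunnel")
#' read_compound_table(path, reference_ids = "MCULE-8293284864")
#' @export
read_compound_table <- function(path, aliases = compound_aliases(),
                                reference_ids = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  nm <- tolower(trimws(names(raw)))
  mapped <- unname(aliases[nm])
  unknown_required <- setdiff(c("id", "affinity_kcal_mol", "ld50_mol_kg"),
                              mapped[!is.na(mapped)])
  if (length(unknown_required)) {
    abort(paste0("compound table is missing required column(s): ",
                 paste(unknown_required, collapse = ", ")))
  }
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  out <- tibble(id = trimws(raw$id))
  if (nrow(out) == 0) {
    return(tibble(
      id = character(), smiles = character(),
      affinity_kcal_mol = numeric(), ld50_mol_kg = numeric(),
      wlogp = numeric(), tpsa = numeric(),
      pgp = logical(), region = character(), is_reference = logical()
    ))
  }
  if (any(!nzchar(out$id))) abort("compound ids must be non-empty")
  out$smiles <- if ("smiles" %in% names(raw)) raw$smiles else NA_character_
  for (col in c("affinity_kcal_mol", "ld50_mol_kg", "wlogp", "tpsa", "distance")) {
    if (col %in% names(raw)) {
      v <- parse_numeric_tolerant(raw[[col]])
      if (length(attr(v, "bad"))) {
        abort(paste0("unparseable numeric in column `", col, "` at row(s) ",
                     paste(attr(v, "bad"), collapse = ", ")))
      }
      attr(v, "bad") <- NULL
      out[[col]] <- v
    } else if (col %in% c("affinity_kcal_mol", "ld50_mol_kg", "wlogp", "tpsa")) {
      out[[col]] <- NA_real_
    }
  }
  if ("ranking" %in% names(raw)) {
    out$ranking <- suppressWarnings(as.integer(parse_numeric_tolerant(raw$ranking)))
  }
  out$pgp <- if ("pgp" %in% names(raw)) parse_pgp(raw$pgp) else NA
  out$region <- if ("region" %in% names(raw)) parse_region(raw$region) else NA_character_
  out$is_reference <- out$id %in% (reference_ids %||% character())
  if (anyDuplicated(out$id)) {
    warn("duplicate compound ids present; see deduplicate_hits()")
  }
  bad_ld50 <- which(!is.na(out$ld50_mol_kg) & out$ld50_mol_kg <= 0)
  if (length(bad_ld50)) {
    abort(paste0("ld50 must be positive; offending row(s): ",
                 paste(bad_ld50, collapse = ", ")))
  }
  out
}

parse_pgp <- function(x) {
  x <- tolower(trimws(normalize_minus(as.character(x))))
  out <- rep(NA, length(x))
  out[x %in% c("+", "yes", "true", "1")] <- TRUE
  out[x %in% c("-", "no", "false", "0")] <- FALSE
  out
}

parse_region <- function(x) {
  x <- trimws(as.character(x))
  ok <- c(HIA = "HIA", BBB = "BBB", OUT = "Out")
  out <- unname(ok[toupper(x)])
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    abort(paste0("unknown BOILED-Egg region value(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Write a ranked hit table
#'
#' Writes ranked hits with a deterministic column order
#' (`ranking, id, affinity_kcal_mol, ld50_mol_kg, distance, region, pgp`)
#' so the file mirrors a published ranking table and round-trips through
#' [read_compound_table()].
#'
#' @param hits A tibble of ranked hits (output of [euclidean_rank()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ranked_table <- function(hits, path) {
  hits <- as_tibble(hits)
  if (nrow(hits)) {
    if (!"ranking" %in% names(hits)) abort("hits must carry a `ranking` column")
    if (anyDuplicated(hits$ranking)) abort("duplicate ranks in ranked table")
    if (!setequal(hits$ranking, seq_len(nrow(hits)))) {
      abort("ranks must be a permutation of 1..n")
    }
  }
  cols <- c("ranking", "id", "affinity_kcal_mol", "ld50_mol_kg",
            "distance", "region", "pgp")
  for (col in cols) if (!col %in% names(hits)) hits[[col]] <- NA
  out <- hits[cols]
  out$pgp <- ifelse(is.na(out$pgp), "", ifelse(out$pgp, "+", "-"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
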