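#' Load a structural-alert catalog
#'
#' The package bundles compact curated catalogs of the two alert families
#' used in qualitative hit triage: `"pains"` (pan-assay interference
#' substructures) and `"brenk"` (reactive/toxic fragments). A custom
#' catalog may be given as a path to a TSV with columns
#' `pattern_id`, `smarts`, `description` (`#` comment lines ignored).
#' Every pattern is validated as parseable SMARTS at load time.
#'
#' @param name `"pains"`, `"brenk"`, or a file path.
#' @return A tibble with class `alert_catalog` and attributes `catalog_name`
#'   and `catalog_version`.
#' @export
load_alert_catalog <- function(name) {
  path <- switch(tolower(name),
    pains = extdata_path("alerts", "pains_compact.tsv"),
    brenk = extdata_path("alerts", "brenk_compact.tsv"),
    name
  )
  if (!file.exists(path)) abort(paste0("alert catalog not found: ", name))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]  # '#' also occurs inside SMARTS
  cat_tbl <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                             show_col_types = FALSE, progress = FALSE)
  need <- c("pattern_id", "smarts", "description")
  if (!all(need %in% names(cat_tbl))) {
    abort("alert catalog needs columns pattern_id, smarts, description")
  }
  if (!nrow(cat_tbl)) abort("alert catalog has no entries")
  bad <- cat_tbl$pattern_id[!vapply(cat_tbl$smarts, ob_smarts_valid, logical(1))]
  if (length(bad)) {
    abort(paste0("malformed SMARTS in catalog entr",
                 if (length(bad) > 1) "ies: " else "y: ",
                 paste(bad, collapse = ", ")))
  }
  structure(cat_tbl,
            class = c("alert_catalog", class(cat_tbl)),
            catalog_name = tolower(basename(path)),
            catalog_version = "compact-1.0")
}

#' Screen a molecule against an alert catalog
#'
#' @param mol A [molecule_graph()].
#' @param catalog An [load_alert_catalog()] result.
#' @return Character vector of matched pattern ids (empty when clean).
#' @export
alert_screen <- function(mol, catalog) {
  stopifnot(inherits(mol, "molecule_graph"))
  if (!inherits(catalog, "alert_catalog")) {
    abort("`catalog` must come from load_alert_catalog()")
  }
  hits <- vapply(catalog$smarts, function(p) ob_smarts_count(mol, p) > 0,
                 logical(1))
  catalog$pattern_id[hits]
}

#' Qualitative drug-likeness gate
#'
#' A molecule passes when it has zero Lipinski violations AND no PAINS
#' matches AND no Brenk matches (all three simultaneously). Published
#' screening services sometimes tolerate one Lipinski violation; set
#' `max_lipinski_violations = 1` to mirror that.
#'
#' @param mol A [molecule_graph()].
#' @param pains,brenk Alert catalogs (defaults: bundled compact catalogs).
#' @param max_lipinski_violations Violations tolerated (default 0).
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   empty when passing; entries like `"Lipinski:mw"`, `"PAINS:<id>"`,
#'   `"Brenk:<id>"`).
#' @export
qualitative_pass <- function(mol,
                             pains = load_alert_catalog("pains"),
                             brenk = load_alert_catalog("brenk"),
                             max_lipinski_violations = 0L) {
  desc <- lipinski_violations(compute_descriptors(mol))
  reasons <- character()
  if (desc$n_violations > max_lipinski_violations) {
    rules <- c(hbd = desc$viol_hbd, hba = desc$viol_hba,
               mw = desc$viol_mw, logp = desc$viol_logp)
    reasons <- c(reasons, paste0("Lipinski:", names(rules)[rules]))
  }
  reasons <- c(reasons, paste0("PAINS:", alert_screen(mol, pains)))
  reasons <- c(reasons, paste0("Brenk:", alert_screen(mol, brenk)))
  reasons <- reasons[!reasons %in% c("PAINS:", "Brenk:")]
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Deduplicate screening hits
#'
#' Keeps the first occurrence of each compound. With `by = "id"` duplicates
#' are repeated identifiers; with `by = "structure"` records sharing a
#' canonical structure key (canonical SMILES via OpenBabel when a `smiles`
#' column is present) collapse even under different ids.
#'
#' @param records A compound tibble ([read_compound_table()] output).
#' @param by `"id"` or `"structure"`.
#' @return The deduplicated tibble, with attribute `n_duplicates`.
#' @export
deduplicate_hits <- function(records, by = c("id", "structure")) {
  by <- match.arg(by)
  records <- as_tibble(records)
  key <- if (by == "id") {
    records$id
  } else {
    if (!"smiles" %in% names(records) || all(is.na(records$smiles))) {
      abort("structure-key deduplication needs a `smiles` column")
    }
    vapply(records$smiles, canonical_smiles, character(1))
  }
  keep <- !duplicated(key)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_duplicates") <- sum(!keep)
  out
}

canonical_smiles <- function(smiles) {
  if (is.na(smiles)) return(NA_character_)
  mol <- parse_smiles(smiles)
  with_obmol(mol, function(ob, obmol) {
    conv <- ob$OBConversion()
    ob$OBConversion_SetOutFormat(conv, "can")
    trimws(ob$OBConversion_WriteString(conv, obmol))
  })
}
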