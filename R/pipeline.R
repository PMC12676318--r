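PIPELINE_SCHEMA <- list(
  seed = "integer",
  input = c("compounds", "structures"),
  reference = c("id", "affinity_kcal_mol", "ld50_mol_kg"),
  ideal = c("affinity_min", "ld50_max"),
  filters = c("dedup_by", "max_lipinski_violations", "use_alerts"),
  output = c("dir", "ranked", "report")
)

validate_config <- function(config) {
  unknown <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (section in c("input", "reference", "filters", "ideal", "output")) {
    sec <- config[[section]]
    if (is.null(sec)) next
    bad <- setdiff(names(sec), PIPELINE_SCHEMA[[section]])
    if (length(bad)) {
      abort(paste0("unknown key(s) in `", section, "`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  need <- c("input", "reference", "output")
  missing <- need[!need %in% names(config)]
  if (length(missing)) {
    abort(paste0("config is missing required section(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(config$input$compounds)) abort("config needs `input.compounds`")
  ref <- config$reference
  for (f in c("id", "affinity_kcal_mol", "ld50_mol_kg")) {
    if (is.null(ref[[f]])) abort(paste0("config needs `reference.", f, "`"))
  }
  if (is.null(config$output$dir)) abort("config needs `output.dir`")
  invisible(config)
}

pipeline_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the triage funnel from a declarative config
#'
#' Single entry point wiring deduplication, the qualitative gate, the
#' quadrant filter, ideal-point ranking, and region annotation from a
#' YAML (or list) configuration. The config is validated against a strict
#' schema before any work: unknown keys are errors, and every threshold
#' used is echoed into the run report so the analysis is auditable. A
#' stage failure aborts with the stage name and attaches the partial
#' report as a condition field. Outputs (`ranked.csv`, `report.json`) are
#' byte-deterministic: the report carries no timestamps.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Sections: `input` (`compounds` CSV path, optional `structures` SDF
#'   path), `reference` (`id`, `affinity_kcal_mol`, `ld50_mol_kg`),
#'   optional `ideal` (`affinity_min`, `ld50_max`), optional `filters`
#'   (`dedup_by`, `max_lipinski_violations`, `use_alerts`), `output`
#'   (`dir`, optional file names `ranked`, `report`), optional `seed`.
#' @param quiet Suppress stage log messages (default `FALSE`).
#' @return A list with class `run_report` (invisibly): stage counts,
#'   parameters, and output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  log <- if (quiet) function(...) invisible() else pipeline_log
  stage <- "setup"
  report <- list(parameters = list(
    seed = config$seed %||% 1L,
    reference = config$reference,
    ideal = config$ideal,
    filters = config$filters %||% list(dedup_by = "id")
  ))
  result <- tryCatch({
    stage <- "read_compounds"
    log("INFO", "reading compound table: ", config$input$compounds)
    records <- read_compound_table(config$input$compounds)
    report$parameters$input <- config$input

    structures <- NULL
    if (!is.null(config$input$structures)) {
      stage <- "read_structures"
      log("INFO", "reading structures: ", config$input$structures)
      mols <- read_structures(config$input$structures)
      structures <- stats::setNames(mols, vapply(mols, function(m) m$name, character(1)))
    }

    stage <- "funnel"
    ref <- config$reference
    ideal <- if (!is.null(config$ideal)) {
      ideal_point(affinity_min = config$ideal$affinity_min,
                  ld50_max = config$ideal$ld50_max)
    }
    use_alerts <- isTRUE(config$filters$use_alerts %||% !is.null(structures))
    funnel <- run_funnel(
      records, reference = ref, ideal = ideal,
      structures = if (use_alerts) structures,
      dedup_by = config$filters$dedup_by %||% "id"
    )
    log("INFO", "stage counts: ",
        paste(names(funnel$report$counts), unlist(funnel$report$counts),
              sep = "=", collapse = " -> "))

    stage <- "write_outputs"
    out_dir <- config$output$dir
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ranked_path <- file.path(out_dir, config$output$ranked %||% "ranked.csv")
    report_path <- file.path(out_dir, config$output$report %||% "report.json")
    if (nrow(funnel$ranked)) write_ranked_table(funnel$ranked, ranked_path)
    report$counts <- funnel$report$counts
    report$funnel <- funnel$report[c("reference", "ideal", "region_source", "catalogs")]
    report$outputs <- list(ranked = ranked_path, report = report_path)
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    log("INFO", "wrote ", ranked_path, " and ", report_path)
    structure(c(report, list(ranked = funnel$ranked)), class = "run_report")
  }, error = function(e) {
    abort(paste0("pipeline failed in stage `", stage, "`: ",
                 conditionMessage(e)),
          class = "pipeline_error", partial_report = report)
  })
  invisible(result)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  stages:",
      paste(names(x$counts), unlist(x$counts), sep = "=", collapse = " -> "),
      "\n  outputs:", unlist(x$outputs), "\n")
  invisible(x)
}
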