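#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a funnel result into its ranked-hit rows
#'
#' @param x A [run_funnel()] result.
#' @param ... Unused.
#' @return The ranked tibble (one row per surviving compound).
#' @export
tidy.funnel_result <- function(x, ...) {
  out <- x$ranked
  class(out) <- setdiff(class(out), c("ranked_hits"))
  as_tibble(out)
}

#' One-row funnel summary
#'
#' @param x A [run_funnel()] result.
#' @param ... Unused.
#' @return A one-row tibble of stage counts plus the ideal point used.
#' @export
glance.funnel_result <- function(x, ...) {
  cnt <- x$report$counts
  out <- as_tibble(cnt)
  if (!is.null(x$report$ideal)) {
    out$ideal_affinity_min <- x$report$ideal$affinity_min
    out$ideal_ld50_max <- x$report$ideal$ld50_max
  }
  out
}

#' Tidy an alignment result into its mismatch table
#'
#' @param x An [align_sequences()] result.
#' @param ... Unused.
#' @return A tibble with one row per mismatching aligned column.
#' @export
tidy.alignment_result <- function(x, ...) {
  x$mismatches
}

#' One-row alignment summary
#'
#' @param x An [align_sequences()] result.
#' @param ... Unused.
#' @return A one-row tibble: identity, coverage, match/mismatch counts,
#'   alignment score.
#' @export
glance.alignment_result <- function(x, ...) {
  tibble(
    identity = x$identity, coverage = x$coverage,
    n_matches = x$n_matches, n_mismatches = x$n_mismatches,
    score = x$score
  )
}

#' Tidy a Ramachandran result into per-residue labels
#'
#' @param x A [rama_classify()] result.
#' @param ... Unused.
#' @return The per-residue tibble with a `label` column.
#' @export
tidy.rama_result <- function(x, ...) {
  as_tibble(x$labels)
}

#' One-row Ramachandran summary
#'
#' @param x A [rama_classify()] result.
#' @param ... Unused.
#' @return A one-row tibble of region counts and percentages.
#' @export
glance.rama_result <- function(x, ...) {
  tibble(
    n_favored = unname(x$counts["favored"]),
    n_allowed = unname(x$counts["allowed"]),
    n_outlier = unname(x$counts["outlier"]),
    pct_favored = unname(x$percent["favored"]),
    pct_allowed = unname(x$percent["allowed"]),
    pct_outlier = unname(x$percent["outlier"])
  )
}

#' @export
print.rama_result <- function(x, ...) {
  cat(sprintf("<rama_result> favored %.2f%%, allowed %.2f%%, outlier %.2f%%\n",
              x$percent["favored"], x$percent["allowed"], x$percent["outlier"]))
  invisible(x)
}
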