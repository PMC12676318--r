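#' ROC curve over active/decoy docking scores
#'
#' Builds the receiver operating characteristic by sweeping a score
#' threshold from best to worst. Docking affinities are "lower is better",
#' so scores are negated internally and the standard higher-is-more-active
#' machinery applies; set `lower_is_better = FALSE` for plain scores.
#' Equal scores collapse into a single step.
#'
#' @param active_scores,decoy_scores Numeric score vectors (both
#'   non-empty, finite).
#' @param lower_is_better Score convention (default `TRUE`, the docking
#'   affinity convention).
#' @return A tibble with class `roc_curve`, columns `threshold`, `fpr`,
#'   `tpr`, starting at (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(active_scores, decoy_scores, lower_is_better = TRUE) {
  check_scores(active_scores, decoy_scores)
  a <- if (lower_is_better) -active_scores else active_scores
  d <- if (lower_is_better) -decoy_scores else decoy_scores
  thr <- sort(unique(c(a, d)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(a >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(d >= t), numeric(1))
  out <- tibble(
    threshold = c(Inf, if (lower_is_better) -thr else thr),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

check_scores <- function(active, decoy) {
  if (!length(active) || !length(decoy)) {
    abort("both active and decoy score sets must be non-empty")
  }
  if (!all(is.finite(active)) || !all(is.finite(decoy))) {
    abort("scores must be finite")
  }
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; numerically identical to the
#' Mann-Whitney probability that a random active outscores a random decoy,
#' with ties counted one half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(-9, -9.5), c(-5, -6))   # perfect separation: 1
#' @export
auc <- function(active_scores, decoy_scores, lower_is_better = TRUE) {
  r <- roc_curve(active_scores, decoy_scores, lower_is_better)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Generate property-matched decoys
#'
#' A deliberately simplified stand-in for web decoy services: draws `n`
#' decoy records whose molecular weight and logP lie within +/-10% of the
#' active's while carrying a distinct structure key. Deterministic under
#' `seed`.
#'
#' @param active A one-row data frame (or list) with `mw` and `logp` (a
#'   descriptor set, see [compute_descriptors()]).
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param strict Error on `n = 0` (default `TRUE`); otherwise return an
#'   empty table.
#' @return A tibble with columns `id`, `mw`, `logp`, `structure_key`.
#' @export
generate_decoys <- function(active, n, seed = 1L, strict = TRUE) {
  if (n < 1) {
    if (strict) abort("`n` must be >= 1")
    return(tibble(id = character(), mw = numeric(), logp = numeric(),
                  structure_key = character()))
  }
  mw <- as.numeric(active$mw[1]); logp <- as.numeric(active$logp[1])
  assert_scalar_finite(mw, "active$mw")
  with_stream_seed(seed, "generate_decoys", {
    tibble(
      id = sprintf("decoy_%04d", seq_len(n)),
      mw = runif(n, mw * 0.9, mw * 1.1),
      logp = logp + runif(n, -abs(logp) * 0.1, abs(logp) * 0.1),
      structure_key = sprintf("synthetic-key-%04d-%06d", seq_len(n),
                              sample.int(999999L, n))
    )
  })
}
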