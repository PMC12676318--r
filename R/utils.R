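#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by
#'   summarise ungroup row_number n distinct across all_of pull rename
#' @importFrom purrr map map_dbl map_int map_lgl map_chr map2 pmap imap keep
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Normalise the assorted unicode dashes that typeset tables use for minus
# signs (en-dash, em-dash, true minus) to an ASCII hyphen before numeric
# parsing.
normalize_minus <- function(x) {
  gsub("[‒–—−]", "-", x)
}

# Parse a numeric column tolerating unicode minus variants; returns NA where
# the value is empty, with attr "bad" holding indices that failed to parse.
parse_numeric_tolerant <- function(x) {
  x <- trimws(normalize_minus(as.character(x)))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  attr(out, "bad") <- bad
  out
}

# Derive a reproducible, generator-specific seed below 2^31 from a user seed
# and a stream name, so adding one generator never perturbs another's draws.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000000L) * 2017L + (h %% 104729L)
}

# Evaluate `code` under a derived seed, restoring the caller's RNG state.
with_stream_seed <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, name))
  force(code)
}

# Shared checker: a numeric scalar, finite.
assert_scalar_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", what, "` must be a single finite number"))
  }
  invisible(x)
}

extdata_path <- function(...) {
  system.file("extdata", ..., package = "hitfunnel", mustWork = TRUE)
}
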