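# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (0.625 -> 0.63), matching
#' the convention used when comparing against values printed at fixed
#' precision.  Base R's `round()` rounds halves to even (0.625 -> 0.62).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.625, 2) # 0.63
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Names of the feature columns of an utterance-style data frame.
feature_cols <- function(x) {
  setdiff(colnames(x), c("subject_id", "state", "utterance_index", "mmse",
                         "group", "cd"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# MD5 of a config list (via its canonical JSON), for provenance stamping.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}
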