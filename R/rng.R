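#' Derive a reproducible substream seed
#'
#' A single pipeline seed is fanned out into independent per-generator
#' substreams keyed by arbitrary labels (e.g. `subject_id`, generator
#' name), so adding a subject does not perturb the draws of another.
#' Polynomial string hashing modulo a Mersenne-adjacent prime keeps the
#' result strictly below 2^31, valid as an R RNG seed.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed in `[1, 2147483628]`.
#' @export
#' @examples
#' substream_seed(1, "gait", "S01") != substream_seed(1, "gait", "S02")
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                      character(1)), collapse = "::")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(1 + (h + (abs(seed) %% m) * 7919) %% (m - 1))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
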