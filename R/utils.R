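#' @keywords internal
#' @useDynLib greenodor, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run code under a local RNG state so package functions are deterministic
# given their seed arguments without clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that each stage
#' (balancing, cross-validation, training, embedding, ...) is independently
#' reproducible. The derivation hashes the stage name into an offset and
#' keeps the result inside the 32-bit integer range R requires.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"cv"` or `"embed"`.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "cv")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (x in utf8ToInt(stage)) h <- (h * 31 + x) %% 1000003
  as.integer((abs(as.numeric(seed)) + h * 2654435.0) %% 2147483647)
}

# integer-safe polynomial hash folded mod 2^31 - 1; inputs are non-negative
# numbers well below 2^42 so the intermediate h * 31 + x stays exact in doubles
hash_mix <- function(xs, init = 17) {
  h <- init
  for (x in xs) h <- (h * 31 + x) %% 2147483647
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
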