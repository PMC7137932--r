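#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' Null-model cells (site x metric x pool x variant) each get their own RNG
#' stream so results do not depend on evaluation order. The key is hashed
#' with FNV-1a and folded into the base seed modulo 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param ... character/numeric components of the cell key.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(key)
  # polynomial rolling hash modulo the Mersenne prime 2^31 - 1; all
  # intermediates stay below 2^53 so double arithmetic is exact
  h <- 17
  for (b in bytes) {
    h <- (h * 1048583 + b) %% 2147483647
  }
  as.integer((h + as.numeric(seed)) %% 2147483646 + 1)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_np <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "nichepack_error")))
}

warn_np <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
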