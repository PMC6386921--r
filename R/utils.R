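# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded fits do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to fingerprint hierarchies and extractor parameters; collision
# resistance at cryptographic strength is not needed here.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h in double to avoid overflow
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hierfusar_error")))
}
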