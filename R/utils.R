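#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used wherever the pipeline needs independent
#' seeded random streams (one per fold, per training-set size, per repeat).
#' Keeps results reproducible end-to-end from a single master seed while
#' avoiding correlated streams. Result is always in `[0, 2^31 - 1)`.
#'
#' @param seed master seed (integer).
#' @param ... further integer components (fold index, size, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
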