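#' Derive a stream-specific seed from a global seed
#'
#' Deterministic mixing of a global integer seed with a stream index, kept
#' within the 32-bit integer range so every stage of a pipeline run can
#' receive its own reproducible seed.
#'
#' @param seed Global integer seed.
#' @param stream Positive integer stream index.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stream) {
  m <- 2147483587
  s <- (abs(as.double(seed)) %% m) + 1
  x <- (s * 48271 + as.double(stream) * 8191) %% m
  as.integer(x + 1)
}

# evaluate expr with a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
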