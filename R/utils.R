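# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed) without clobbering the caller's RNG
# stream. All generators route their randomness through this so that every
# emitted object is a pure function of (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# Reverse complement of an A/C/G/T/N character vector of sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
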