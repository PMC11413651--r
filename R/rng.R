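# Seed handling.  All stochastic operations run inside with_seed() so they are
# reproducible without clobbering the caller's RNG state.  Sub-streams are
# derived from a master seed with derive_seed() and kept below 2^31 - 1.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from (seed, tag, index); multiplicative-congruential
# mix kept inside 32-bit integer range.
derive_seed <- function(seed, tag, index = 0L) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  s <- (as.double(seed) * 48271 + h * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(s) + 1L
}
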