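# Run code with a private RNG stream: seeds deterministically, restores the
# caller's .Random.seed afterwards so library calls never clobber user state.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside the
# 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483647)
}
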