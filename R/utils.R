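# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported generators route their
# randomness through this so they are pure functions of (params, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  have <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (have) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Derive a child seed from a top-level seed; keeps results within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 1103L + as.double(offset) * 12345L) %% 2147483587
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_vims <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
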