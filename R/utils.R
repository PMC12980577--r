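# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed, staying well inside
# 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(k) %% 1009L
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop("`", name, "` must be a finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be positive", call. = FALSE)
  }
  invisible(x)
}
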