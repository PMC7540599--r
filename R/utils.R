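# Internal helpers shared across the package.

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream. All exported samplers route their randomness through this so that
# (args, seed) fully determine the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be coercible to integer", call. = FALSE)
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible sub-seed stream from a master seed, kept within the
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Format doubles so that read-back with as.numeric() is bit-exact.
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

`%||%` <- function(a, b) if (is.null(a)) b else a
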