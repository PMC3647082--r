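# Internal helpers.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic substream seed derived from a master seed; kept < 2^31 - 1.
derive_seed <- function(seed, offset) {
  x <- ((as.numeric(seed) %% 2147483647) * 7919 + offset * 104729) %% 2147483629
  as.integer(x) + 1L
}

# Commercial (half-up) rounding; base round() rounds half to even, which is
# not how percentages are conventionally reported.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop("`", name, "` must be a single nonnegative integer", call. = FALSE)
  }
}
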