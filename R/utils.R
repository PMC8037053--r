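# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and one or more stream indices,
# kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 7919 + as.double(i) * 104729 + 1) %% 2147483587
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cogload <- function(...) stop(sprintf(...), call. = FALSE)

warn_cogload <- function(...) warning(sprintf(...), call. = FALSE)

# Guarded division: denominator floored at eps in magnitude (sign preserved
# for negative denominators). Returns list(value, guarded flag).
guard_ratio <- function(num, den, eps) {
  guarded <- abs(den) < eps
  den2 <- ifelse(guarded, eps * ifelse(den < 0, -1, 1), den)
  list(value = num / den2, guarded = guarded)
}
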