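# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All user-facing seeded operations go
# through this so that library code never perturbs the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and one or more indices, staying
# within the 32-bit signed integer range R requires.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + 1234567 + as.double(i)) %% 2147483647
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}
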