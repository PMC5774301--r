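# Internal numerical helpers.

# exp() that saturates instead of overflowing; fitting explores extreme
# slopes where raw exponents exceed the double range.
exp_safe <- function(x) {
  exp(pmin(x, 700))
}

# Evaluate a block with a locally-set RNG seed, restoring the caller's
# RNG state afterwards. `seed = NULL` uses the ambient RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit signed integer range. Used to fan one top-level seed out to
# independent per-sample / per-model streams.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index)) %% 2147483647)
}

stopifnot_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}
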