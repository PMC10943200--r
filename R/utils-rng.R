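# Evaluate an expression under a fixed RNG seed, restoring the caller's
# generator state afterwards so seeded package internals never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
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
  expr
}

# Derive a reproducible child seed from a parent seed and a label, staying
# within the 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
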