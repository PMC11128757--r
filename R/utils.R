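# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 32-bit polynomial hash of a character string, as 8 hex
# digits. Used to stamp artifacts with the configuration that produced them.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Stable seed in [0, 2^31) derived from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  bytes <- as.integer(charToRaw(as.character(tag)))
  h <- as.double(seed) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}
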