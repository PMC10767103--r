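# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
# Every stochastic entry point takes an explicit seed and routes through
# this, so pipeline stages are individually reproducible and do not disturb
# the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop("seed must be a single finite number", call. = FALSE)
    }
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
  }
  expr
}

# Derive a child seed from a parent seed and stage labels, keeping the
# result inside the positive 32-bit integer range. FNV-1a string hash --
# stable across platforms, avoids a digest dependency.
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "/")
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
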