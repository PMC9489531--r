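# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and an index, staying inside 32-bit
# integer range.  Multiplicative hashing keeps distinct (seed, index) pairs
# from colliding for the small indices used here.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  v <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483629
  as.integer(v %% 2147483562) + 1L
}

# FNV-1a style rolling hash over the serialization of an R object.
# Used for manifest config hashes; not cryptographic.
hash_object <- function(x) {
  b <- serialize(x, connection = NULL, version = 2L)
  v <- as.integer(b)
  h <- 2166136261
  m <- 2^32
  # process in chunks with a vectorized polynomial fold to keep this fast
  p <- 16777619
  for (i in seq_len(ceiling(length(v) / 256L))) {
    lo <- (i - 1L) * 256L + 1L
    hi <- min(i * 256L, length(v))
    chunk <- v[lo:hi]
    for (ci in chunk) {
      h <- ((h %% 2^24) * p + bitwXor(as.integer(h %% 2^16), ci)) %% m
    }
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# clamp a numeric vector to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
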