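# Internal numerical helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

## log(sum(exp(x))) without overflow; x may be a matrix (rowwise reduction)
logsumexp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

## Gauss-Legendre nodes/weights on [a, b], cached per node count.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gl_cache[[key]]
}

## Rescale unit GL rule to [a, b] (vectors a, b allowed, recycled)
gl_rescale <- function(rule, a, b) {
  half <- (b - a) / 2
  list(
    x = outer(half, rule$x) + (a + b) / 2, # length(a) x n
    w = outer(half, rule$w)
  )
}

## Gauss-Hermite nodes (physicists' convention: integral of exp(-x^2) f(x))
.gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  }
  .gh_cache[[key]]
}

## ---- 32-bit avalanche hashing for reproducible substreams --------------
## All arithmetic on doubles kept below 2^53 so it is exact; vectorized.

xor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

mul32 <- function(a, b) {
  a1 <- a %/% 65536; a0 <- a %% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

## murmur3 32-bit finalizer: full avalanche
mix32 <- function(x) {
  x <- xor32(x, x %/% 65536)
  x <- mul32(x, 2246822507)
  x <- xor32(x, x %/% 8192)
  x <- mul32(x, 3266489909)
  xor32(x, x %/% 65536)
}

## Fold an arbitrary tag (number or string) to a 32-bit key.
hash_key <- function(tg) {
  if (is.numeric(tg)) return(round(tg * 65536) %% 4294967296)
  vapply(as.character(tg), function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 4294967296
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## Combine a master seed and tags into well-separated 32-bit hashes.
## Tags may be vectors (recycled to a common length).
hash32 <- function(master, ...) {
  keys <- lapply(list(...), hash_key)
  h <- mix32((as.numeric(master) %% 4294967296) + 2654435769)
  for (k in keys) h <- mix32(xor32(h, k))
  h
}

## Standard-normal deviates keyed by (master, tags): deterministic,
## collision-resistant, independent across distinct tag combinations.
## Box-Muller on two hashed uniforms.
hash_normal <- function(master, ...) {
  u1 <- (hash32(master, ..., 1) + 0.5) / 4294967296
  u2 <- (hash32(master, ..., 2) + 0.5) / 4294967296
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

## Substream seed for set.seed() derived from a master seed and tags.
mix_seed <- function(master, ...) {
  as.integer(hash32(master, ...) %% 2147483629 + 1)
}

## Quantile with the linear-interpolation convention used throughout (type 7).
qtl <- function(x, p) unname(quantile(x, p, type = 7, na.rm = TRUE))

## Format "median (p25-p75)" strings for reports.
fmt_med_iqr <- function(x, digits = 1) {
  q <- qtl(x, c(0.25, 0.5, 0.75))
  sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
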