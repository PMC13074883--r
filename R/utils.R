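# Internal helpers: seed derivation and small numeric utilities.

# Deterministically derive a 32-bit-safe sub-seed from a base seed and any
# number of string/number keys. Plain polynomial string hash; good enough
# to decorrelate per-image / per-variant RNG streams.
deriveSeed <- function(seed, ...) {
  keys <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(keys)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable content hash of an R object (polynomial hash over its deparsed
# form); used to stamp run artifacts with the resolved configuration.
contentHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(txt)) {
    h <- (h * 31 + code) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
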