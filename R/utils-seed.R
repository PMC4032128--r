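# Deterministic seed fan-out. A single user-facing seed is expanded into
# independent per-gene / per-stage streams so results do not depend on the
# order in which genes are processed.

# 31-bit polynomial string hash; the small multiplier keeps every
# intermediate product below 2^53 so the arithmetic is exact in doubles
hash_string <- function(x) {
  h <- 216613
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# derive a child seed from a parent seed and a string label
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 + hash_string(label)) %% 2147483647)
}

# evaluate `expr` under a temporary RNG state seeded by (seed, label)
with_stream <- function(seed, label, expr) {
  withr::with_seed(derive_seed(seed, label), expr)
}
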