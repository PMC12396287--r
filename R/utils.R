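# Internal helpers shared across modules.

# Round half away from zero (printed cohort tables use half-up, e.g. 12.5 -> 13,
# which base round() does not do).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

# Cosine similarity between one row and all rows of a matrix.
cosine_to_all <- function(vectors, node) {
  v <- vectors[node, ]
  nv <- sqrt(sum(v^2))
  norms <- sqrt(rowSums(vectors^2))
  sims <- as.numeric(vectors %*% v) / (norms * nv)
  sims[!is.finite(sims)] <- 0
  names(sims) <- rownames(vectors)
  sims
}

# Stable 31-bit string hash (polynomial rolling hash); used to derive
# per-node RNG streams so walks do not depend on node insertion order.
string_hash31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647L
  as.integer(h)
}

# Combine a user seed with a string into a valid 32-bit seed.
derive_seed <- function(seed, s) {
  as.integer((as.numeric(seed) * 7919 + string_hash31(s)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
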