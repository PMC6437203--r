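# Internal numerical helpers shared across modules.

# Derive a reproducible sub-stream seed from a global seed and a stream name.
# Counter-based (Knuth multiplicative hash of the name folded into the seed)
# so adding a new generator never shifts the draws of existing ones.
streamSeed <- function(seed, stream) {
  h <- sum(as.numeric(utf8ToInt(stream)) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sums <- rowSums(x)
  # all-zero rows can occur for very small alpha; fall back to a point mass
  zero <- sums == 0
  if (any(zero)) {
    for (i in which(zero)) x[i, sample.int(length(alpha), 1)] <- 1
    sums <- rowSums(x)
  }
  x / sums
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
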