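# Independent oracles and fixture builders used across the suite.

# --- Weir & Cockerham (1984) theta, coded independently of the package ----
# Variance-components estimator from a GenotypeTable: per allele per locus,
# components a (among populations), b (among individuals within), c (within
# individuals), summed over alleles and loci.
wcFst <- function(gt) {
  pops <- sort(unique(gt@pop))
  r <- length(pops)
  num <- den <- 0
  for (l in seq_along(gt@loci)) {
    a1 <- gt@alleles[, l, 1]; a2 <- gt@alleles[, l, 2]
    ok <- !is.na(a1)
    if (!any(ok)) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    n_i <- vapply(pops, function(p) sum(ok & gt@pop == p), 0)
    if (any(n_i == 0)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(pops, function(p) {
        idx <- ok & gt@pop == p
        (sum(a1[idx] == al) + sum(a2[idx] == al)) / (2 * sum(idx))
      }, 0)
      h_i <- vapply(pops, function(p) {
        idx <- ok & gt@pop == p
        sum((a1[idx] == al) != (a2[idx] == al)) / sum(idx)
      }, 0)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# --- exhaustive rarefaction oracle -----------------------------------------
# Mean number of distinct classes over ALL C(N, g) subsamples of the
# gene-copy multiset implied by `counts`.
rarefactionBruteForce <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# --- grid-search oracle for the 2-source mixture likelihood ----------------
# Maximizes the conditional mixture log-likelihood over pi_1 on a fixed
# grid, using the same per-individual source log-likelihood matrix.
gridSearchPi <- function(logf, step = 0.001) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(p) {
    lp <- cbind(logf[, 1] + log(p), logf[, 2] + log(1 - p))
    mx <- pmax(lp[, 1], lp[, 2])
    mx[!is.finite(mx)] <- 0
    sum(mx + log(exp(lp[, 1] - mx) + exp(lp[, 2] - mx)))
  }, 0)
  grid[which.max(ll)]
}

# --- small fixture builders ------------------------------------------------
# Two-source baselines fixed for disjoint alleles at one locus.
diagnosticFixture <- function(nA = 12, n = 30, nBase = 50) {
  # rows 1..nBase are srcA (allele 101), rest srcB (102)
  arr <- array(NA_integer_, dim = c(2 * nBase, 1, 2))
  arr[seq_len(nBase), 1, ] <- 101L
  arr[nBase + seq_len(nBase), 1, ] <- 102L
  base <- genotypeTable(sprintf("b%03d", 1:(2 * nBase)),
                        rep(c("srcA", "srcB"), each = nBase), arr, "loc1")
  mixArr <- array(NA_integer_, dim = c(n, 1, 2))
  mixArr[seq_len(nA), 1, ] <- 101L
  mixArr[nA + seq_len(n - nA), 1, ] <- 102L
  mix <- genotypeTable(sprintf("m%03d", 1:n), "mixture", mixArr, "loc1")
  list(baselines = alleleCounts(base), mixture = mix, base_gt = base)
}

expect_simplex <- function(x, tol = 1e-9) {
  testthat::expect_true(all(x >= -tol))
  testthat::expect_lt(abs(sum(x) - 1), 1e-8)
}
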