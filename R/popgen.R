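#' Tabulate per-population, per-locus allele counts
#'
#' Missing genotypes are excluded per locus, so counts at a locus total
#' twice the number of successfully typed individuals in each population.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @return An \linkS4class{AlleleFrequencyTable}.
#' @export
alleleCounts <- function(gt) {
  stopifnot(is(gt, "GenotypeTable"), length(gt) >= 1)
  pops <- sort(unique(gt@pop))
  counts <- vector("list", length(gt@loci))
  names(counts) <- gt@loci
  for (l in seq_along(gt@loci)) {
    copies <- c(gt@alleles[, l, 1L], gt@alleles[, l, 2L])
    poplab <- rep(gt@pop, 2L)
    ok <- !is.na(copies)
    codes <- sort(unique(copies[ok]))
    m <- matrix(0L, length(pops), max(length(codes), 1L),
                dimnames = list(pops,
                                if (length(codes)) sprintf("%03d", codes) else "000"))
    if (length(codes)) {
      tab <- table(factor(poplab[ok], levels = pops),
                   factor(copies[ok], levels = codes))
      m[] <- as.integer(tab)
    }
    counts[[l]] <- m
  }
  new("AlleleFrequencyTable", pops = pops, loci = gt@loci, counts = counts)
}

#' Relative allele frequencies of an AlleleFrequencyTable
#'
#' @param aft an \linkS4class{AlleleFrequencyTable}.
#' @return list of matrices (populations x alleles) with rows summing to 1;
#'   rows with zero copies are all-NA.
#' @export
alleleFrequencies <- function(aft) {
  stopifnot(is(aft, "AlleleFrequencyTable"))
  lapply(aft@counts, function(m) {
    s <- rowSums(m)
    f <- sweep(m, 1, pmax(s, 1), "/")
    f[s == 0, ] <- NA_real_
    f
  })
}

# Rarefied expected number of distinct classes in a subsample of g copies
# drawn without replacement from N copies with class counts n_a:
#   sum_a [1 - C(N - n_a, g) / C(N, g)]
rarefiedRichness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1) stop("rarefaction size g must be >= 1")
  if (N == 0) return(NA_real_)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness per locus and population
#'
#' Expected number of distinct alleles among \code{g} gene copies sampled
#' without replacement, removing sample-size bias so populations typed at
#' different depths are comparable.
#'
#' @param aft an \linkS4class{AlleleFrequencyTable}.
#' @param g rarefaction size in gene copies; default twice the smallest
#'   per-locus sample size across populations.
#' @return list with \code{per_locus} (matrix populations x loci),
#'   \code{mean} (per-population average over loci) and \code{g}.
#' @export
allelicRichness <- function(aft, g = NULL) {
  stopifnot(is(aft, "AlleleFrequencyTable"))
  sizes <- vapply(aft@counts, rowSums, numeric(length(aft@pops)))
  if (is.null(dim(sizes))) sizes <- matrix(sizes, nrow = length(aft@pops))
  if (is.null(g)) g <- min(sizes[sizes > 0])
  if (g < 1) stop("rarefaction size g must be >= 1")
  per <- matrix(NA_real_, length(aft@pops), length(aft@loci),
                dimnames = list(aft@pops, aft@loci))
  for (l in seq_along(aft@loci))
    for (k in seq_along(aft@pops))
      per[k, l] <- rarefiedRichness(aft@counts[[l]][k, ], g)
  list(per_locus = per, mean = rowMeans(per, na.rm = TRUE), g = g)
}

#' Rarefied haplotype richness
#'
#' Same rarefaction formula as \link{allelicRichness}, applied to haploid
#' haplotype counts.
#'
#' @param counts integer vector of haplotype counts (one population), or a
#'   matrix populations x haplotypes.
#' @param g rarefaction size (haploid copies); default the smallest
#'   population total when \code{counts} is a matrix, else \code{sum(counts)}.
#' @return numeric value, or named vector for a matrix input.
#' @export
haplotypeRichness <- function(counts, g = NULL) {
  if (is.matrix(counts)) {
    if (is.null(g)) g <- min(rowSums(counts))
    return(apply(counts, 1, rarefiedRichness, g = g))
  }
  if (is.null(g)) g <- sum(counts)
  rarefiedRichness(counts, g)
}

#' Unbiased expected heterozygosity per locus and population
#'
#' Nei's unbiased gene diversity \code{(2n/(2n-1)) (1 - sum p_i^2)} with
#' \code{n} the number of typed individuals. Undefined (NA) below two
#' individuals.
#'
#' @param aft an \linkS4class{AlleleFrequencyTable}.
#' @return list with \code{per_locus} (matrix populations x loci) and
#'   \code{mean} (per-population average over loci).
#' @export
expectedHeterozygosity <- function(aft) {
  stopifnot(is(aft, "AlleleFrequencyTable"))
  per <- matrix(NA_real_, length(aft@pops), length(aft@loci),
                dimnames = list(aft@pops, aft@loci))
  for (l in seq_along(aft@loci)) {
    m <- aft@counts[[l]]
    N <- rowSums(m)                       # gene copies = 2n
    p2 <- rowSums(sweep(m, 1, pmax(N, 1), "/")^2)
    he <- N / (N - 1) * (1 - p2)
    he[N < 4] <- NA_real_
    per[, l] <- he
  }
  list(per_locus = per, mean = rowMeans(per, na.rm = TRUE))
}

#' Haplotype diversity
#'
#' \code{h = (n/(n-1)) (1 - sum p_i^2)} for haploid counts.
#'
#' @param counts integer vector of haplotype counts (one population) or a
#'   matrix populations x haplotypes.
#' @return numeric value or per-population named vector.
#' @export
haplotypeDiversity <- function(counts) {
  one <- function(x) {
    n <- sum(x)
    if (n < 2) return(NA_real_)
    n / (n - 1) * (1 - sum((x / n)^2))
  }
  if (is.matrix(counts)) apply(counts, 1, one) else one(counts)
}

#' Per-site nucleotide diversity of an alignment
#'
#' Average pairwise proportion of differing sites, computed over sites with
#' no gap or N in any sequence (complete deletion):
#' \code{pi = sum_{i<j} d_ij / (C(n,2) L)}.
#'
#' @param aln a \linkS4class{HaplotypeAlignment} with >= 2 sequences.
#' @return numeric per-site diversity.
#' @export
nucleotideDiversity <- function(aln) {
  stopifnot(is(aln, "HaplotypeAlignment"), length(aln) >= 2)
  mat <- do.call(rbind, strsplit(as.character(aln@seqs), ""))
  keep <- colSums(mat == "-" | mat == "N") == 0
  if (!any(keep)) stop("complete deletion removed every site")
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat); L <- ncol(mat)
  total <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      total <- total + sum(mat[i, ] != mat[j, ])
  total / (choose(n, 2) * L)
}

# Multinomial log-likelihood-ratio (G) statistic of a 2 x A count table
gStatistic <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- tab[tab > 0]
  2 * sum(o * log(o / e[tab > 0]))
}

#' Permutation test of population differentiation
#'
#' Tests homogeneity of allele (or haplotype) frequencies between two
#' populations with the multinomial G statistic, permuting individuals
#' (or haploid copies) between the populations. Per-locus p-values are
#' combined by Fisher's method. Permutation statistics tied with the
#' observed one count as at least as extreme, and
#' \code{p = (1 + #[perm >= obs]) / (n_perm + 1)}.
#'
#' @param x a \linkS4class{GenotypeTable} (diploid; individuals permuted),
#'   or a 2-row count matrix of haploid category counts (copies permuted).
#' @param popA,popB population labels to compare (GenotypeTable input only).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with \code{per_locus} (named p-value vector), \code{p}
#'   (Fisher-combined), \code{statistics} (observed G per locus).
#' @export
permDiffTest <- function(x, popA = NULL, popB = NULL, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (is(x, "GenotypeTable")) {
    sel <- x@pop %in% c(popA, popB)
    if (!any(x@pop == popA) || !any(x@pop == popB))
      stop("both populations must be present")
    g <- x[sel]
    lab <- g@pop == popA
    perLocusG <- function(labels) {
      vapply(seq_along(g@loci), function(l) {
        copies <- c(g@alleles[, l, 1L], g@alleles[, l, 2L])
        grp <- rep(labels, 2L)
        ok <- !is.na(copies)
        if (!any(ok & grp) || !any(ok & !grp)) return(NA_real_)
        tab <- table(grp[ok], copies[ok])
        gStatistic(unclass(tab))
      }, 0)
    }
    obs <- perLocusG(lab)
    exceed <- rep(0L, length(obs))
    withSeed(streamSeed(seed, "perm_diff"), {
      for (b in seq_len(n_perm)) {
        permG <- perLocusG(sample(lab))
        exceed <- exceed + as.integer(!is.na(permG) & !is.na(obs) &
                                        permG >= obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
    p[is.na(obs)] <- NA_real_
    names(p) <- names(obs) <- g@loci
  } else {
    tab <- as.matrix(x)
    if (nrow(tab) != 2) stop("count-matrix input must have exactly 2 rows")
    if (any(rowSums(tab) == 0)) stop("a population with zero copies is undefined")
    obs <- gStatistic(tab)
    units <- rep(seq_len(ncol(tab)), colSums(tab))
    n1 <- rowSums(tab)[1]
    exceed <- 0L
    withSeed(streamSeed(seed, "perm_diff"), {
      for (b in seq_len(n_perm)) {
        idx <- sample(length(units), n1)
        t1 <- tabulate(units[idx], nbins = ncol(tab))
        permTab <- rbind(t1, colSums(tab) - t1)
        exceed <- exceed + as.integer(gStatistic(permTab) >= obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
    names(p) <- names(obs) <- "haploid"
  }
  ok <- !is.na(p)
  combined <- if (sum(ok) == 0) NA_real_ else
    stats::pchisq(-2 * sum(log(p[ok])), df = 2 * sum(ok), lower.tail = FALSE)
  list(per_locus = p, p = combined, statistics = obs)
}

#' Per-population diversity report
#'
#' Assembles rarefied allelic richness, unbiased expected heterozygosity
#' and (when an alignment is supplied) haplotype richness, haplotype
#' diversity and nucleotide diversity into one table.
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param aln optional \linkS4class{HaplotypeAlignment} on the same
#'   populations.
#' @param g rarefaction size in gene copies (see \link{allelicRichness}).
#' @return data.frame, one row per population.
#' @export
diversityReport <- function(gt, aln = NULL, g = NULL) {
  aft <- alleleCounts(gt)
  ar <- allelicRichness(aft, g)
  he <- expectedHeterozygosity(aft)
  out <- data.frame(population = aft@pops,
                    allelic_richness = ar$mean,
                    expected_heterozygosity = he$mean,
                    rarefaction_g = ar$g,
                    row.names = NULL)
  if (!is.null(aln)) {
    ch <- collapseHaplotypes(aln)
    hr <- haplotypeRichness(ch$counts)
    hd <- haplotypeDiversity(ch$counts)
    pops <- rownames(ch$counts)
    pi_by_pop <- vapply(pops, function(p) {
      idx <- which(aln@pop == p)
      if (length(idx) < 2) return(NA_real_)
      nucleotideDiversity(new("HaplotypeAlignment",
                              seqs = aln@seqs[idx], pop = aln@pop[idx]))
    }, 0)
    hapdf <- data.frame(population = pops, haplotype_richness = hr,
                        haplotype_diversity = hd,
                        nucleotide_diversity = pi_by_pop, row.names = NULL)
    out <- merge(out, hapdf, by = "population", all = TRUE)
  }
  out
}
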