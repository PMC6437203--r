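#' @import methods
#' @importFrom stats optimize rmultinom rnorm runif rbinom setNames coef lm
#'   step AIC pt pnorm nls quantile var sd rlnorm as.dist hclust pchisq
#'   median formula as.formula resid vcov qnorm
#' @importFrom utils head tail
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Diploid multilocus genotypes with population labels
#'
#' The atom of all genetic analyses: one row per individual, one slice per
#' locus, two allele codes per genotype. Allele codes are positive integers
#' (microsatellite convention: 2- or 3-digit codes); a missing genotype is a
#' pair of \code{NA}s.
#'
#' @slot ids character vector of individual identifiers.
#' @slot pop character vector of population labels, parallel to \code{ids}.
#' @slot loci character vector of locus names.
#' @slot alleles integer array of dimension \code{c(n, L, 2)} holding the two
#'   allele codes per individual and locus; both \code{NA} when missing.
#' @export
setClass("GenotypeTable",
  representation(ids = "character", pop = "character",
                 loci = "character", alleles = "array"))

setValidity("GenotypeTable", function(object) {
  n <- length(object@ids); L <- length(object@loci)
  a <- object@alleles
  if (!is.integer(a) && !all(is.na(a))) return("allele array must be integer")
  if (length(dim(a)) != 3L || !all(dim(a) == c(n, L, 2L)))
    return(sprintf("allele array must have dimension c(%d, %d, 2)", n, L))
  if (length(object@pop) != n) return("pop labels must parallel ids")
  if (any(!nzchar(object@pop))) return("population labels must be non-empty")
  if (L < 1L) return("at least one locus is required")
  if (any(a <= 0L, na.rm = TRUE)) return("allele codes must be positive")
  half <- is.na(a[, , 1L, drop = FALSE]) != is.na(a[, , 2L, drop = FALSE])
  if (any(half)) return("half-missing genotypes are not allowed")
  TRUE
})

#' Construct a GenotypeTable
#'
#' @param ids individual identifiers.
#' @param pop population labels (recycled if length 1).
#' @param alleles integer array \code{c(n, L, 2)} of allele codes, \code{NA}
#'   for missing genotypes.
#' @param loci locus names.
#' @return A \linkS4class{GenotypeTable}.
#' @export
genotypeTable <- function(ids, pop, alleles, loci) {
  if (length(pop) == 1L) pop <- rep(pop, length(ids))
  storage.mode(alleles) <- "integer"
  new("GenotypeTable", ids = as.character(ids), pop = as.character(pop),
      loci = as.character(loci), alleles = alleles)
}

#' @describeIn GenotypeTable-class number of individuals
#' @param x,object a \code{GenotypeTable}
#' @export
setMethod("length", "GenotypeTable", function(x) length(x@ids))

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@ids), "individuals,",
      length(object@loci), "loci,",
      length(unique(object@pop)), "populations\n")
  miss <- mean(is.na(object@alleles[, , 1, drop = FALSE]))
  cat("  loci:", paste(head(object@loci, 5), collapse = ", "),
      if (length(object@loci) > 5) "..." else "", "\n")
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
})

#' Population labels of a genetic container
#' @param x a \code{GenotypeTable} or \code{HaplotypeAlignment}.
#' @return character vector of per-individual population labels.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname populations
#' @export
setMethod("populations", "GenotypeTable", function(x) x@pop)

#' Locus names
#' @param x a \code{GenotypeTable} or \code{AlleleFrequencyTable}.
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname lociNames
#' @export
setMethod("lociNames", "GenotypeTable", function(x) x@loci)

#' Subset a GenotypeTable by individuals
#' @param x a \code{GenotypeTable}
#' @param i index vector over individuals
#' @param j,...,drop ignored
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  genotypeTable(x@ids[i], x@pop[i],
                x@alleles[i, , , drop = FALSE], x@loci)
})

#' Per-population, per-locus allele counts
#'
#' Counts of gene copies per allele, with sample sizes implied by row sums.
#' Missing genotypes are excluded per locus, so a population's gene-copy
#' total at a locus is twice its number of successfully typed individuals.
#'
#' @slot pops population labels (rows of every count matrix).
#' @slot loci locus names.
#' @slot counts list, one integer matrix per locus (populations x alleles);
#'   column names are allele codes.
#' @export
setClass("AlleleFrequencyTable",
  representation(pops = "character", loci = "character", counts = "list"))

setValidity("AlleleFrequencyTable", function(object) {
  if (length(object@counts) != length(object@loci))
    return("one count matrix per locus required")
  for (m in object@counts) {
    if (!is.matrix(m) || nrow(m) != length(object@pops))
      return("count matrices must have one row per population")
    if (any(m < 0)) return("counts must be nonnegative")
  }
  TRUE
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  nal <- vapply(object@counts, ncol, 0L)
  cat("AlleleFrequencyTable:", length(object@pops), "populations,",
      length(object@loci), "loci,", sum(nal), "alleles total\n")
})

#' @rdname lociNames
#' @export
setMethod("lociNames", "AlleleFrequencyTable", function(x) x@loci)

#' @rdname populations
#' @export
setMethod("populations", "AlleleFrequencyTable", function(x) x@pops)

#' Aligned mtDNA haplotype sequences with population labels
#'
#' Wraps a \code{Biostrings::DNAStringSet} of equal-width aligned sequences
#' (alphabet A, C, G, T, N, -) together with a population label per
#' sequence.
#'
#' @slot seqs a \code{DNAStringSet}; names are sequence ids.
#' @slot pop character vector of population labels.
#' @export
setClass("HaplotypeAlignment",
  representation(seqs = "DNAStringSet", pop = "character"))

setValidity("HaplotypeAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    return("all sequences must share one alignment length")
  if (length(object@pop) != length(object@seqs))
    return("one population label per sequence required")
  letters <- unique(strsplit(paste(as.character(object@seqs), collapse = ""),
                             "")[[1]])
  bad <- setdiff(letters, c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    return(paste("disallowed alignment character(s):",
                 paste(bad, collapse = ", ")))
  TRUE
})

setMethod("show", "HaplotypeAlignment", function(object) {
  cat("HaplotypeAlignment:", length(object@seqs), "sequences x",
      if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0,
      "bp,", length(unique(object@pop)), "populations\n")
})

#' @rdname populations
#' @export
setMethod("populations", "HaplotypeAlignment", function(x) x@pop)

#' @describeIn HaplotypeAlignment-class number of sequences
#' @param x,object a \code{HaplotypeAlignment}
#' @export
setMethod("length", "HaplotypeAlignment", function(x) length(x@seqs))

#' Mixture-proportion estimate from genetic stock identification
#'
#' @slot proportions named vector of estimated source proportions (sum 1).
#' @slot seMixture mixture-sampling SE component (inverse observed
#'   information of the conditional likelihood).
#' @slot seBaseline baseline-sampling SE component (parametric resampling).
#' @slot seTotal combined SE, \code{sqrt(seMixture^2 + seBaseline^2)}.
#' @slot ci matrix of bootstrap percentile intervals (sources x 2), or a
#'   0-row matrix when bootstrapping was not requested.
#' @slot posteriors matrix of per-individual source posteriors at the
#'   optimum (rows sum to 1).
#' @slot logLik conditional log-likelihood at the optimum.
#' @slot iterations EM iterations used by the best start.
#' @slot converged logical convergence flag.
#' @slot excluded ids of mixture individuals with zero likelihood under all
#'   sources (dropped with a warning).
#' @export
setClass("MixtureEstimate",
  representation(proportions = "numeric", seMixture = "numeric",
                 seBaseline = "numeric", seTotal = "numeric",
                 ci = "matrix", posteriors = "matrix", logLik = "numeric",
                 iterations = "integer", converged = "logical",
                 excluded = "character"))

setValidity("MixtureEstimate", function(object) {
  p <- object@proportions
  if (any(p < -1e-12)) return("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) return("proportions must sum to 1")
  if (nrow(object@posteriors) &&
      max(abs(rowSums(object@posteriors) - 1)) > 1e-6)
    return("posterior rows must sum to 1")
  TRUE
})

setMethod("show", "MixtureEstimate", function(object) {
  cat("MixtureEstimate (conditional-ML GSI)\n")
  tab <- data.frame(proportion = round(object@proportions, 4),
                    se = round(object@seTotal, 4))
  if (nrow(object@ci)) {
    tab$ci_lo <- round(object@ci[, 1], 4)
    tab$ci_hi <- round(object@ci[, 2], 4)
  }
  print(tab)
  cat(sprintf("logLik %.3f after %d EM iterations (%s)\n", object@logLik,
              object@iterations,
              if (object@converged) "converged" else "NOT converged"))
})

#' Source proportions of a MixtureEstimate
#' @param object a \code{MixtureEstimate}.
#' @return named numeric vector summing to 1.
#' @export
setGeneric("mixingProportions", function(object) standardGeneric("mixingProportions"))

#' @rdname mixingProportions
#' @export
setMethod("mixingProportions", "MixtureEstimate", function(object) object@proportions)

#' Standard errors of a MixtureEstimate
#' @param object a \code{MixtureEstimate}.
#' @param component one of "total", "mixture", "baseline".
#' @export
setGeneric("standardErrors",
           function(object, component = "total") standardGeneric("standardErrors"))

#' @rdname standardErrors
#' @export
setMethod("standardErrors", "MixtureEstimate", function(object, component = "total") {
  switch(match.arg(component, c("total", "mixture", "baseline")),
         total = object@seTotal, mixture = object@seMixture,
         baseline = object@seBaseline)
})

#' Exponential-decline fit y = a exp(-lambda x)
#'
#' @slot amplitude fitted amplitude a.
#' @slot rate fitted per-year decline rate lambda.
#' @slot seAmplitude,seRate asymptotic standard errors.
#' @slot tStat,pValue,df t statistic and two-sided p for lambda != 0.
#' @slot fitted,residuals fitted values and residuals on the original scale.
#' @slot method "nls" or "loglinear" (fallback when nls fails).
#' @slot converged logical.
#' @export
setClass("DecayFit",
  representation(amplitude = "numeric", rate = "numeric",
                 seAmplitude = "numeric", seRate = "numeric",
                 tStat = "numeric", pValue = "numeric", df = "numeric",
                 fitted = "numeric", residuals = "numeric",
                 method = "character", converged = "logical"))

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: y = %.4f exp(-%.4f x)  [%s]\n", object@amplitude,
              object@rate, object@method))
  cat(sprintf("  rate SE %.4f, t = %.3f, P = %.3g (df = %d)\n",
              object@seRate, object@tStat, object@pValue, object@df))
})

#' Per-year decline rate of a DecayFit
#' @param object a \code{DecayFit}.
#' @param se logical; return the standard error instead of the estimate.
#' @export
setGeneric("decayRate", function(object, se = FALSE) standardGeneric("decayRate"))

#' @rdname decayRate
#' @export
setMethod("decayRate", "DecayFit",
          function(object, se = FALSE) if (se) object@seRate else object@rate)

#' Trajectory of the wild-gene replacement recursion
#'
#' @slot states matrix of genotype proportions per generation
#'   (columns WW, WH, HH; row 1 is generation 0).
#' @slot wildGene wild-gene proportion p_t per generation
#'   (\code{WW + WH/2}).
#' @slot equilibrium wild-gene proportion at convergence.
#' @slot converged logical; FALSE when the iteration cap was hit first.
#' @slot f,R hatchery fitness and stocking rate used.
#' @export
setClass("ReplacementTrajectory",
  representation(states = "matrix", wildGene = "numeric",
                 equilibrium = "numeric", converged = "logical",
                 f = "numeric", R = "numeric"))

setValidity("ReplacementTrajectory", function(object) {
  s <- object@states
  if (ncol(s) != 3L) return("states must have columns WW, WH, HH")
  if (any(s < -1e-9) || any(abs(rowSums(s) - 1) > 1e-9))
    return("genotype proportions must form a probability simplex")
  TRUE
})

setMethod("show", "ReplacementTrajectory", function(object) {
  cat(sprintf("ReplacementTrajectory: f = %g, R = %g, %d generations\n",
              object@f, object@R, nrow(object@states) - 1L))
  cat(sprintf("  wild-gene proportion: 1 -> %.4g (equilibrium %.4g, %s)\n",
              tail(object@wildGene, 1), object@equilibrium,
              if (object@converged) "converged" else "not converged"))
})

#' Wild-gene proportion per generation
#' @param object a \code{ReplacementTrajectory}.
#' @return numeric vector, element t+1 is generation t.
#' @export
setGeneric("wildGeneProportion", function(object) standardGeneric("wildGeneProportion"))

#' @rdname wildGeneProportion
#' @export
setMethod("wildGeneProportion", "ReplacementTrajectory",
          function(object) object@wildGene)
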