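# Empirical Bayes pairwise F_ST via a Dirichlet-multinomial hierarchy.
#
# Model: the two populations' true allele-frequency vectors at each locus
# are Dirichlet(theta * pbar) around the pooled frequencies pbar, and the
# observed allele counts are multinomial draws from those vectors. Under
# this hierarchy Wright's F_ST equals 1/(1 + theta), so a single scale
# hyperparameter shared across loci captures pairwise differentiation;
# estimating theta by marginal maximum likelihood shrinks noisy per-locus
# signals, which is what makes the estimator usable for weakly
# differentiated, high-gene-flow populations.

dirMultLogLik <- function(ltheta, countsA, countsB, pbars) {
  theta <- exp(ltheta)
  ll <- 0
  for (l in seq_along(pbars)) {
    ab <- theta * pbars[[l]]
    for (n in list(countsA[[l]], countsB[[l]])) {
      N <- sum(n)
      ll <- ll + lgamma(theta) - lgamma(theta + N) +
        sum(lgamma(ab + n) - lgamma(ab))
    }
  }
  ll
}

#' Empirical Bayes pairwise F_ST for one population pair
#'
#' Maximizes the product over loci of Dirichlet-multinomial marginal
#' likelihoods in the shared concentration \code{theta} (1-D optimization
#' on the log scale over [1e-4, 1e6]) and reports
#' \code{F_ST = 1/(1 + theta_hat)}.
#'
#' With only the pair available, \code{pbar} defaults to the pair's pooled
#' sample frequencies. That plug-in loses half the between-population
#' degrees of freedom (deviations are measured about the pair's own mean),
#' which biases very weak differentiation towards zero; when the pair is
#' part of a larger survey, pass the survey-wide pooled frequencies as
#' \code{pbar} instead, as \link{ebFst} does.
#'
#' @param countsA,countsB lists of per-locus allele-count vectors on a
#'   shared allele indexing (e.g. rows of an
#'   \linkS4class{AlleleFrequencyTable}'s count matrices).
#' @param pbar optional list of per-locus baseline frequency vectors
#'   (the Dirichlet mean), aligned with the count vectors.
#' @return list with \code{fst}, \code{theta}, \code{logLik},
#'   \code{converged} (FALSE when the optimum sits on the search boundary).
#' @export
ebFstPair <- function(countsA, countsB, pbar = NULL) {
  stopifnot(length(countsA) == length(countsB))
  keep <- vapply(seq_along(countsA),
                 function(l) sum(countsA[[l]]) > 0 && sum(countsB[[l]]) > 0,
                 TRUE)
  if (!any(keep)) stop("populations share no typed locus")
  countsA <- countsA[keep]; countsB <- countsB[keep]
  pbars <- vector("list", length(countsA))
  if (!is.null(pbar)) pbar <- pbar[keep]
  for (l in seq_along(countsA)) {
    base <- if (is.null(pbar)) countsA[[l]] + countsB[[l]] else pbar[[l]]
    ok <- base > 0
    if (any(countsA[[l]][!ok] > 0) || any(countsB[[l]][!ok] > 0))
      stop("pbar assigns zero frequency to an observed allele")
    countsA[[l]] <- countsA[[l]][ok]
    countsB[[l]] <- countsB[[l]][ok]
    pbars[[l]] <- base[ok] / sum(base[ok])
  }
  opt <- stats::optimize(dirMultLogLik, interval = log(c(1e-4, 1e6)),
                         countsA = countsA, countsB = countsB, pbars = pbars,
                         maximum = TRUE, tol = 1e-8)
  theta <- exp(opt$maximum)
  atBoundary <- opt$maximum < log(1e-4) + 1e-4 || opt$maximum > log(1e6) - 1e-4
  list(fst = 1 / (1 + theta), theta = theta, logLik = opt$objective,
       converged = !atBoundary)
}

#' Empirical Bayes pairwise F_ST matrix
#'
#' Applies \link{ebFstPair} to every population pair of an allele-count
#' table (microsatellite counts) or a haplotype-count matrix. The Dirichlet
#' mean \code{pbar} for every pair is the survey-wide pooled frequency
#' (counts summed over all populations), which keeps the pairwise estimates
#' nearly unbiased even for very weak differentiation.
#'
#' Plugging the P-population pooled mean in as the Dirichlet mean shrinks
#' the measurable between-population dispersion: for P exchangeable
#' populations the mean squared deviation of a sample frequency from the
#' pooled mean is \code{(P-1)/P} of its variance (Bessel's factor), and
#' \code{1/P} of the multinomial sampling noise is absorbed into the pool.
#' Inverting that first-order relation gives the finite-pool correction
#' \code{F = (d + 1/(N P)) P/(P-1)} applied to each pair's fitted
#' dispersion \code{d = 1/(1 + theta_hat)}, with \code{N} the harmonic-mean
#' gene copies per population. Without it, weak differentiation (the
#' high-gene-flow regime this estimator targets) is biased towards zero.
#'
#' @param x an \linkS4class{AlleleFrequencyTable}, or an integer matrix of
#'   haploid haplotype counts (populations x haplotypes).
#' @return list of class \code{"EBFstMatrix"}: \code{fst} and \code{theta}
#'   (symmetric matrices, zero diagonal, consistent via
#'   \code{F = 1/(1+theta)}), \code{converged} (logical matrix),
#'   \code{mean} and \code{sd} of the off-diagonal F_ST values.
#' @export
ebFst <- function(x) {
  if (is(x, "AlleleFrequencyTable")) {
    pops <- x@pops
    getCounts <- function(k) lapply(x@counts, function(m) m[k, ])
    pbar <- lapply(x@counts, function(m) {
      tot <- colSums(m)
      tot / sum(tot)
    })
    copies <- rowMeans(vapply(x@counts, rowSums, numeric(length(pops))))
  } else {
    x <- as.matrix(x)
    pops <- rownames(x) %||% sprintf("pop%d", seq_len(nrow(x)))
    getCounts <- function(k) list(x[k, ])
    pbar <- list(colSums(x) / sum(x))
    copies <- rowSums(x)
  }
  P <- length(pops)
  if (P < 2) stop("need at least two populations")
  nTilde <- 1 / mean(1 / copies[copies > 0])   # harmonic-mean copies per pop
  correct <- function(d)
    min(max((d + 1 / (nTilde * P)) * P / (P - 1), 1e-6), 1 - 1e-6)
  fst <- theta <- matrix(0, P, P, dimnames = list(pops, pops))
  conv <- matrix(TRUE, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    ci <- getCounts(i)
    for (j in (i + 1):P) {
      r <- ebFstPair(ci, getCounts(j), pbar = pbar)
      f <- if (P > 2) correct(r$fst) else r$fst
      fst[i, j] <- fst[j, i] <- f
      theta[i, j] <- theta[j, i] <- 1 / f - 1
      conv[i, j] <- conv[j, i] <- r$converged
    }
  }
  off <- fst[upper.tri(fst)]
  structure(list(fst = fst, theta = theta, converged = conv,
                 mean = mean(off), sd = stats::sd(off)),
            class = "EBFstMatrix")
}

#' @export
print.EBFstMatrix <- function(x, ...) {
  cat("EBFstMatrix:", nrow(x$fst), "populations; mean pairwise F_ST",
      format(x$mean, digits = 4), "+/-", format(x$sd, digits = 4), "(s.d.)\n")
  if (!all(x$converged)) cat("  warning: some pairs hit the search boundary\n")
  invisible(x)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance,
#' so root-to-leaf path lengths are equal (ultrametric). Labels are sorted
#' lexicographically before clustering, which makes tie-breaks
#' deterministic (the pair containing the lexicographically smallest member
#' is merged first among equals).
#'
#' @param d symmetric distance matrix with labels (e.g. the \code{fst}
#'   element of \link{ebFst}), or a \code{dist}.
#' @return an ultrametric \code{ape::phylo} tree.
#' @export
upgmaTree <- function(d) {
  m <- as.matrix(d)
  if (any(!is.finite(m))) stop("distance matrix contains non-finite entries")
  if (nrow(m) < 2) stop("need at least two leaves")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- sprintf("L%d", seq_len(nrow(m)))
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}
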