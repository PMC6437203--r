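# Conditional-maximum-likelihood genetic stock identification.
#
# The mixture likelihood L(pi) = prod_i sum_k pi_k f_k(x_i) is maximized by
# EM with baseline allele frequencies held fixed at their (smoothed) sample
# estimates -- the "conditional" formulation. Baseline sampling error is
# handled separately in the standard errors (parametric resampling of the
# baseline counts), mirroring the two-component SE decomposition of
# classical GSI software.

# Smoothed per-source genotype log-likelihood matrix (n x K).
# Baseline frequencies get pseudo-count 1/A per allele (A = alleles at the
# locus, over the union of baseline and mixture alleles), so mixture alleles
# unseen in a baseline keep a small positive likelihood.
gsiLogLikMatrix <- function(mixture, baselines) {
  stopifnot(is(mixture, "GenotypeTable"), is(baselines, "AlleleFrequencyTable"))
  loci <- intersect(mixture@loci, baselines@loci)
  if (!length(loci)) stop("mixture and baselines share no locus")
  K <- length(baselines@pops)
  n <- length(mixture)
  logf <- matrix(0, n, K, dimnames = list(mixture@ids, baselines@pops))
  for (loc in loci) {
    lm_ <- match(loc, mixture@loci)
    lb <- match(loc, baselines@loci)
    cnt <- baselines@counts[[lb]]
    codesB <- as.integer(colnames(cnt))
    codesM <- unique(stats::na.omit(c(mixture@alleles[, lm_, ])))
    universe <- sort(union(codesB, codesM))
    A <- length(universe)
    full <- matrix(0, K, A, dimnames = list(baselines@pops, universe))
    full[, as.character(codesB)] <- cnt
    N <- rowSums(full)
    p <- (full + 1 / A) / (N + 1)          # K x A smoothed frequencies
    a1 <- mixture@alleles[, lm_, 1L]
    a2 <- mixture@alleles[, lm_, 2L]
    ok <- !is.na(a1)
    i1 <- match(a1[ok], universe)
    i2 <- match(a2[ok], universe)
    het <- i1 != i2
    for (k in seq_len(K)) {
      gl <- log(p[k, i1]) + log(p[k, i2]) + log(2) * het
      logf[ok, k] <- logf[ok, k] + gl
    }
  }
  logf
}

emCore <- function(logf, pi0, tol, max_iter) {
  n <- nrow(logf); K <- ncol(logf)
  pi <- pi0
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(logf, 2, log(pmax(pi, 1e-300)), "+")
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    stopifnot(ll >= ll_prev - 1e-8 * (abs(ll_prev) + 1))  # EM monotonicity
    post <- w / rs
    piNew <- colMeans(post)
    done <- max(abs(piNew - pi)) < tol
    pi <- piNew
    ll_prev <- ll
    if (done) return(list(pi = pi, post = post, logLik = ll,
                          iterations = it, converged = TRUE))
  }
  list(pi = pi, post = post, logLik = ll_prev, iterations = max_iter,
       converged = FALSE)
}

#' Conditional-ML mixture-proportion estimation (EM)
#'
#' Estimates the composition of a mixed sample from baseline allele
#' frequencies of candidate source populations. Loci are assumed
#' independent (HWE genotype probabilities within each source). Multiple
#' random EM starts guard against local optima; the per-iteration
#' log-likelihood is asserted non-decreasing.
#'
#' @param mixture a \linkS4class{GenotypeTable} of mixture individuals.
#' @param baselines an \linkS4class{AlleleFrequencyTable} of the candidate
#'   sources (e.g. \code{alleleCounts(baseline_genotypes)}).
#' @param tol EM stopping tolerance on \code{max |delta pi|}.
#' @param max_iter iteration cap per start.
#' @param n_starts number of starts: uniform plus \code{n_starts - 1}
#'   Dirichlet(1) random starts.
#' @param seed integer seed for the random starts.
#' @return A \linkS4class{MixtureEstimate} with the mixture-sampling SE
#'   filled in; see \link{baselineAwareSE} and \link{bootstrapCI} for the
#'   baseline component and percentile intervals.
#' @export
emEstimate <- function(mixture, baselines, tol = 1e-7, max_iter = 10000L,
                       n_starts = 10L, seed = 1L) {
  if (tol <= 0) stop("tol must be positive")
  logf <- gsiLogLikMatrix(mixture, baselines)
  K <- ncol(logf)
  dead <- apply(logf, 1, function(r) all(!is.finite(r)))
  excluded <- rownames(logf)[dead]
  if (length(excluded)) {
    warning(length(excluded),
            " mixture individual(s) had zero likelihood under every source",
            " and were excluded: ", paste(excluded, collapse = ", "))
    logf <- logf[!dead, , drop = FALSE]
  }
  if (K == 1L) {
    post <- matrix(1, nrow(logf), 1, dimnames = dimnames(logf))
    return(new("MixtureEstimate",
               proportions = stats::setNames(1, colnames(logf)),
               seMixture = stats::setNames(0, colnames(logf)),
               seBaseline = stats::setNames(NA_real_, colnames(logf)),
               seTotal = stats::setNames(0, colnames(logf)),
               ci = matrix(numeric(0), 0, 2), posteriors = post,
               logLik = sum(logf), iterations = 0L, converged = TRUE,
               excluded = excluded))
  }
  starts <- withSeed(streamSeed(seed, "em_starts"), {
    rbind(rep(1 / K, K), rdirichlet(max(n_starts - 1L, 0L), rep(1, K)))
  })
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- emCore(logf, starts[s, ], tol, max_iter)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  pi <- stats::setNames(pmax(best$pi, 0), colnames(logf))
  pi <- pi / sum(pi)
  seMix <- gsiInformationSE(logf, pi)
  new("MixtureEstimate", proportions = pi,
      seMixture = seMix,
      seBaseline = stats::setNames(rep(NA_real_, K), names(pi)),
      seTotal = seMix,
      ci = matrix(numeric(0), 0, 2),
      posteriors = best$post, logLik = best$logLik,
      iterations = as.integer(best$iterations), converged = best$converged,
      excluded = excluded)
}

# Mixture-sampling SE from the observed information of the conditional
# likelihood at pi-hat (free parameters pi_1..pi_{K-1}, outer-product form).
gsiInformationSE <- function(logf, pi) {
  n <- nrow(logf); K <- ncol(logf)
  lp <- sweep(logf, 2, log(pmax(pi, 1e-300)), "+")
  mx <- apply(lp, 1, max)
  logmix <- mx + log(rowSums(exp(lp - mx)))
  u <- exp(logf - logmix)                 # u_ik = f_ik / sum_j pi_j f_ij
  d <- u[, -K, drop = FALSE] - u[, K]
  info <- crossprod(d)
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V))
    return(stats::setNames(rep(NA_real_, K), colnames(logf)))
  se <- sqrt(pmax(diag(V), 0))
  seK <- sqrt(max(sum(V), 0))             # var(1 - sum of free params)
  stats::setNames(c(se, seK), colnames(logf))
}

#' Baseline-aware standard errors for a mixture estimate
#'
#' Total SE^2 = mixture-sampling component (inverse observed information)
#' plus a baseline-sampling component obtained by parametric resampling of
#' the baseline allele counts (multinomial with the observed sample sizes),
#' re-running EM from the point estimate, and taking the empirical variance
#' across resamples.
#'
#' @param est a converged \linkS4class{MixtureEstimate} from
#'   \link{emEstimate}.
#' @param mixture,baselines the inputs used for \code{est}.
#' @param n_resample number of baseline resamples.
#' @param seed integer seed.
#' @param tol,max_iter EM controls for the resample fits.
#' @return \code{est} with \code{seBaseline} and \code{seTotal} filled in.
#'   If the information matrix was singular, \code{seTotal} falls back to
#'   the resampling component alone.
#' @export
baselineAwareSE <- function(est, mixture, baselines, n_resample = 200L,
                            seed = 1L, tol = 1e-7, max_iter = 10000L) {
  stopifnot(is(est, "MixtureEstimate"))
  if (!est@converged) warning("estimate is flagged as non-converged")
  pis <- matrix(NA_real_, n_resample, length(est@proportions))
  withSeed(streamSeed(seed, "baseline_se"), {
    for (b in seq_len(n_resample)) {
      bs <- baselines
      for (l in seq_along(bs@counts)) {
        m <- bs@counts[[l]]
        for (k in seq_len(nrow(m))) {
          N <- sum(m[k, ])
          if (N > 0)
            m[k, ] <- drop(stats::rmultinom(1, N, m[k, ] / N))
        }
        bs@counts[[l]] <- m
      }
      logf <- gsiLogLikMatrix(mixture, bs)
      logf <- logf[apply(logf, 1, function(r) any(is.finite(r))), , drop = FALSE]
      pis[b, ] <- emCore(logf, est@proportions, tol, max_iter)$pi
    }
  })
  seB <- apply(pis, 2, stats::sd)
  names(seB) <- names(est@proportions)
  est@seBaseline <- seB
  est@seTotal <- ifelse(is.na(est@seMixture), seB,
                        sqrt(est@seMixture^2 + seB^2))
  est
}

#' Bootstrap percentile confidence intervals for mixture proportions
#'
#' Resamples mixture individuals and baseline gene copies with replacement,
#' re-estimates, and reports 2.5/97.5 percentiles per source.
#'
#' @param mixture,baselines as in \link{emEstimate}.
#' @param n_boot number of bootstrap replicates (>= 99).
#' @param seed integer seed.
#' @param tol,max_iter,n_starts EM controls for the bootstrap fits
#'   (few starts by default for speed).
#' @return matrix (sources x 2) of lower/upper 95\% bounds, with the
#'   bootstrap proportion draws in attribute \code{"samples"}.
#' @export
bootstrapCI <- function(mixture, baselines, n_boot = 1000L, seed = 1L,
                        tol = 1e-7, max_iter = 10000L, n_starts = 2L) {
  if (n_boot < 99) stop("n_boot must be >= 99")
  K <- length(baselines@pops)
  pis <- matrix(NA_real_, n_boot, K, dimnames = list(NULL, baselines@pops))
  n <- length(mixture)
  withSeed(streamSeed(seed, "gsi_boot"), {
    for (b in seq_len(n_boot)) {
      mixb <- mixture[sample.int(n, n, replace = TRUE)]
      bs <- baselines
      for (l in seq_along(bs@counts)) {
        m <- bs@counts[[l]]
        for (k in seq_len(nrow(m))) {
          N <- sum(m[k, ])
          if (N > 0) m[k, ] <- drop(stats::rmultinom(1, N, m[k, ] / N))
        }
        bs@counts[[l]] <- m
      }
      logf <- gsiLogLikMatrix(mixb, bs)
      logf <- logf[apply(logf, 1, function(r) any(is.finite(r))), , drop = FALSE]
      best <- NULL
      starts <- rbind(rep(1 / K, K), rdirichlet(max(n_starts - 1L, 0L), rep(1, K)))
      for (s in seq_len(nrow(starts))) {
        fit <- emCore(logf, starts[s, ], tol, max_iter)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
      }
      pis[b, ] <- best$pi
    }
  })
  ci <- t(apply(pis, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "samples") <- pis
  ci
}

#' Per-individual source posteriors at the estimated proportions
#'
#' @param est a \linkS4class{MixtureEstimate}.
#' @return data.frame: individual id, posterior per source, MAP source.
#' @export
assignIndividuals <- function(est) {
  stopifnot(is(est, "MixtureEstimate"))
  post <- est@posteriors
  data.frame(id = rownames(post), as.data.frame(post),
             map_source = colnames(post)[max.col(post, ties.method = "first")],
             row.names = NULL, check.names = FALSE)
}
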