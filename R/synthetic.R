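#' Simulation configuration for the synthetic monitoring data generator
#'
#' One validated object parameterizes every generator: multi-population
#' microsatellite baselines under a Dirichlet island model, Hardy-Weinberg
#' genotype sampling, mixture samples with known source proportions,
#' release-cohort recapture series with exponential decline, and covariate
#' time series with a known linear signal.
#'
#' Defaults mirror the monitored red sea bream program: a per-year decline
#' rate of 0.139 in cumulative recapture rates, an initial cumulative
#' recapture rate of 6\% (age-1 curve amplitude), 27-year series, and
#' regression effect sizes equal to the selected-model estimates (intercept
#' 254.48, habitat 0.0982, effort -0.1226, two inert covariates).
#'
#' @param seed integer global seed; each generator derives its own stream.
#' @param n_populations number of baseline populations.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus integer vector (recycled) of allele counts.
#' @param target_fst expected Wright's F_ST among populations, in [0, 1).
#' @param sample_sizes individuals sampled per population (recycled).
#' @param mixture_proportions true source proportions of the mixture sample.
#' @param decay_rate per-year exponential decline rate of cohort recapture
#'   rates (lambda >= 0).
#' @param initial_recapture cumulative recapture rate of the first cohort.
#' @param years length of the simulated series (release cohorts / covariate
#'   years).
#' @param noise_sd sd of the multiplicative lognormal noise on cohort
#'   recapture rates.
#' @param regression_noise_sd sd (response units, tonnes) of the additive
#'   Gaussian noise on the simulated wild catch.
#' @param regression_coefficients true linear coefficients: intercept then
#'   one per covariate (habitat, effort, sst, ph).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(seed = 1L,
                      n_populations = 2L,
                      n_loci = 5L,
                      alleles_per_locus = 10L,
                      target_fst = 0.05,
                      sample_sizes = 50L,
                      mixture_proportions = c(0.423, 0.577),
                      decay_rate = 0.139,
                      initial_recapture = 0.06,
                      years = 27L,
                      noise_sd = 0.2,
                      regression_noise_sd = 55,
                      regression_coefficients = c(254.48, 0.0982, -0.1226, 0, 0)) {
  alleles_per_locus <- rep_len(as.integer(alleles_per_locus), n_loci)
  sample_sizes <- rep_len(as.integer(sample_sizes), n_populations)
  stopifnot(length(seed) == 1, is.finite(seed))
  if (target_fst < 0 || target_fst >= 1)
    stop("target_fst must lie in [0, 1)")
  if (any(sample_sizes < 1)) stop("sample_sizes must all be >= 1")
  if (any(mixture_proportions < 0))
    stop("mixture_proportions must be nonnegative")
  if (abs(sum(mixture_proportions) - 1) > 1e-9)
    stop("mixture_proportions must sum to 1 (within 1e-9)")
  if (decay_rate < 0) stop("decay_rate must be >= 0")
  if (noise_sd < 0 || regression_noise_sd < 0) stop("noise sds must be >= 0")
  if (initial_recapture < 0 || initial_recapture > 1)
    stop("initial_recapture must be a proportion")
  if (any(alleles_per_locus < 2)) stop("each locus needs >= 2 alleles")
  structure(list(seed = as.integer(seed),
                 n_populations = as.integer(n_populations),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = alleles_per_locus,
                 target_fst = target_fst,
                 sample_sizes = sample_sizes,
                 mixture_proportions = mixture_proportions,
                 decay_rate = decay_rate,
                 initial_recapture = initial_recapture,
                 years = as.integer(years),
                 noise_sd = noise_sd,
                 regression_noise_sd = regression_noise_sd,
                 regression_coefficients = regression_coefficients),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig (seed", x$seed, ")\n")
  cat("  populations:", x$n_populations, " loci:", x$n_loci,
      " target F_ST:", x$target_fst, "\n")
  cat("  cohorts:", x$years, "years, decay", x$decay_rate,
      ", lognormal noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Simulate per-population baseline allele frequencies (island model)
#'
#' Each population's frequency vector at a locus is drawn from a Dirichlet
#' distribution with mean \code{pbar} (the metapopulation frequency) and
#' concentration \code{(1 - F_ST)/F_ST}, so the expected Wright's F_ST among
#' populations is approximately \code{target_fst}. With \code{target_fst = 0}
#' all populations share \code{pbar} exactly.
#'
#' @param config a \link{simConfig} object.
#' @param pbar optional list (one numeric vector per locus) of metapopulation
#'   frequencies; by default drawn from a flat Dirichlet per locus.
#' @return list of class \code{"BaselineFrequencies"}: one matrix per locus
#'   (populations x alleles, rows summing to 1), with 3-digit allele codes as
#'   column names.
#' @export
simulateBaselineFrequencies <- function(config, pbar = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  pops <- sprintf("pop%02d", seq_len(config$n_populations))
  withSeed(streamSeed(config$seed, "baseline_frequencies"), {
    freqs <- vector("list", config$n_loci)
    names(freqs) <- sprintf("locus%02d", seq_len(config$n_loci))
    for (l in seq_len(config$n_loci)) {
      A <- config$alleles_per_locus[l]
      pb <- if (is.null(pbar)) drop(rdirichlet(1, rep(1, A))) else pbar[[l]]
      stopifnot(length(pb) == A, abs(sum(pb) - 1) < 1e-9)
      if (config$target_fst == 0) {
        m <- matrix(pb, nrow = length(pops), ncol = A, byrow = TRUE)
      } else {
        theta <- (1 - config$target_fst) / config$target_fst
        if (theta <= 0) stop("island-model concentration must be positive")
        m <- rdirichlet(length(pops), theta * pb)
      }
      dimnames(m) <- list(pops, sprintf("%03d", 100 + seq_len(A)))
      freqs[[l]] <- m
    }
    structure(freqs, class = "BaselineFrequencies")
  })
}

#' Simulate diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Gene copies are drawn independently per locus from each population's
#' frequency vector (HWE, no linkage).
#'
#' @param freqs a \code{"BaselineFrequencies"} list from
#'   \link{simulateBaselineFrequencies}.
#' @param n_per_pop integer vector of individuals per population (recycled).
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeTable}.
#' @export
simulateGenotypes <- function(freqs, n_per_pop, seed = 1L) {
  stopifnot(inherits(freqs, "BaselineFrequencies"))
  pops <- rownames(freqs[[1]])
  n_per_pop <- rep_len(as.integer(n_per_pop), length(pops))
  if (any(n_per_pop <= 0)) stop("n_per_pop must be positive")
  n <- sum(n_per_pop)
  loci <- names(freqs)
  arr <- array(NA_integer_, dim = c(n, length(loci), 2L))
  poplab <- rep(pops, n_per_pop)
  withSeed(streamSeed(seed, "genotypes"), {
    for (l in seq_along(loci)) {
      codes <- as.integer(colnames(freqs[[l]]))
      row0 <- 0L
      for (k in seq_along(pops)) {
        nk <- n_per_pop[k]
        copies <- sample(codes, 2L * nk, replace = TRUE, prob = freqs[[l]][k, ])
        arr[row0 + seq_len(nk), l, 1L] <- copies[seq_len(nk)]
        arr[row0 + seq_len(nk), l, 2L] <- copies[nk + seq_len(nk)]
        row0 <- row0 + nk
      }
    }
  })
  genotypeTable(sprintf("ind%04d", seq_len(n)), poplab, arr, loci)
}

#' Simulate a mixture sample with known source origins
#'
#' Each mixture individual's source is drawn from \code{proportions}; its
#' genotype is then drawn under HWE from that source's allele-frequency
#' estimates (computed from the baseline genotypes). True origins are
#' returned so recovery can be scored.
#'
#' @param baselines a \linkS4class{GenotypeTable} of baseline individuals,
#'   one population per source.
#' @param proportions numeric vector of true source proportions (one per
#'   baseline population, in the order of \code{sort(unique(pop))}).
#' @param n number of mixture individuals (0 allowed).
#' @param seed integer seed.
#' @return list with elements \code{mixture} (a \code{GenotypeTable}, all
#'   labelled "mixture") and \code{origin} (character vector of true source
#'   populations).
#' @export
simulateMixture <- function(baselines, proportions, n, seed = 1L) {
  stopifnot(is(baselines, "GenotypeTable"))
  sources <- sort(unique(baselines@pop))
  if (length(proportions) != length(sources))
    stop("need exactly one proportion per baseline population")
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("proportions must be nonnegative and sum to 1")
  loci <- baselines@loci
  aft <- alleleCounts(baselines)
  arr <- array(NA_integer_, dim = c(n, length(loci), 2L))
  origin <- character(n)
  if (n > 0) {
    withSeed(streamSeed(seed, "mixture"), {
      origin <- sample(sources, n, replace = TRUE, prob = proportions)
      for (l in seq_along(loci)) {
        cnt <- aft@counts[[l]]
        codes <- as.integer(colnames(cnt))
        for (k in seq_along(sources)) {
          rows <- which(origin == sources[k])
          if (!length(rows)) next
          pk <- cnt[sources[k], ]
          if (sum(pk) == 0) stop("baseline ", sources[k], " has no data at ", loci[l])
          copies <- sample(codes, 2L * length(rows), replace = TRUE,
                           prob = pk / sum(pk))
          arr[rows, l, 1L] <- copies[seq_along(rows)]
          arr[rows, l, 2L] <- copies[length(rows) + seq_along(rows)]
        }
      }
    })
  }
  mix <- genotypeTable(sprintf("mix%04d", seq_len(n)), rep("mixture", n),
                       arr, loci)
  list(mixture = mix, origin = origin)
}

#' Simulate release cohorts with exponentially declining recapture rates
#'
#' Cohort \code{y} (0-based) has true cumulative recapture rate
#' \code{r0 * exp(-lambda * y)}, perturbed by multiplicative lognormal noise
#' \code{exp(N(0, noise_sd^2))}. Recaptures-by-age decline geometrically with
#' age and are modulated by a linearly declining fishing-effort index, so
#' that the effort-corrected cumulative rate up to the plus group recovers
#' the (noisy) cohort rate exactly.
#'
#' @param config a \link{simConfig}; uses \code{years}, \code{decay_rate},
#'   \code{initial_recapture} and \code{noise_sd}.
#' @param n_released juveniles released per cohort.
#' @param age_ratio geometric decline of recaptures across ages 1..8.
#' @return list of class \code{"ReleaseCohortSeries"}: \code{cohorts}
#'   (data.frame: release_year, n_released, true_rate), \code{recaptures}
#'   (matrix cohorts x ages 1..8, effort-modulated expected counts),
#'   \code{effort} (data.frame: year, effort) and \code{weight_by_age}
#'   (kg at ages 1..8).
#' @export
simulateReleaseCohorts <- function(config, n_released = 10000L,
                                   age_ratio = 0.55) {
  stopifnot(inherits(config, "SimulationConfig"))
  Y <- config$years
  release_year <- seq_len(Y)
  ages <- 1:8
  w_age <- age_ratio^(ages - 1); w_age <- w_age / sum(w_age)
  years_all <- seq_len(Y + 8L)
  effort <- seq(1, 0.6, length.out = length(years_all))
  rates <- withSeed(streamSeed(config$seed, "release_cohorts"), {
    config$initial_recapture * exp(-config$decay_rate * (release_year - 1)) *
      exp(stats::rnorm(Y, 0, config$noise_sd))
  })
  rec <- matrix(0, Y, length(ages),
                dimnames = list(release_year, paste0("age", ages)))
  for (y in seq_len(Y)) {
    cal <- release_year[y] + ages            # calendar year of each recapture age
    rec[y, ] <- n_released * rates[y] * w_age * effort[cal] / effort[1]
  }
  structure(list(
    cohorts = data.frame(release_year = release_year,
                         n_released = rep(n_released, Y),
                         true_rate = rates),
    recaptures = rec,
    effort = data.frame(year = years_all, effort = effort),
    weight_by_age = stats::setNames(0.3 + 0.45 * (ages - 1), paste0("age", ages))),
    class = "ReleaseCohortSeries")
}

#' Simulate the catch/effort/covariate time series
#'
#' Emulates the covariates of the wild-catch attribution analysis: a rising
#' habitat (seaweed harvest) index, a linearly declining fishing-effort
#' index, and two inert covariates (sea-surface temperature and hatchery
#' fraction). The response is the stated linear combination plus Gaussian
#' noise; the true coefficients are recorded in the attributes.
#'
#' @param config a \link{simConfig}; uses \code{years},
#'   \code{regression_coefficients} (intercept, hijiki, effort, sst, ph) and
#'   \code{regression_noise_sd}.
#' @return data.frame (class \code{"TimeSeriesTable"}) with columns
#'   year, wild_catch, hijiki, effort, sst, ph; attribute
#'   \code{"true_coefficients"} holds the generating coefficients.
#' @export
simulateCatchCovariates <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  beta <- config$regression_coefficients
  if (length(beta) != 5L)
    stop("regression_coefficients must be intercept + 4 covariate effects")
  n <- config$years
  withSeed(streamSeed(config$seed, "catch_covariates"), {
    # harvest and effort carry strong interannual variability around their
    # trends, as the observed series do; without it the two trends would be
    # nearly collinear and neither effect would be separable
    hijiki <- seq(200, 1500, length.out = n) + stats::rnorm(n, 0, 300)
    effort <- seq(2000, 800, length.out = n) + stats::rnorm(n, 0, 250)
    sst <- 20 + stats::rnorm(n, 0, 0.5)
    ph <- pmax(seq(0.55, 0.01, length.out = n) + stats::rnorm(n, 0, 0.03), 0)
    X <- cbind(1, hijiki, effort, sst, ph)
    wild_catch <- drop(X %*% beta) + stats::rnorm(n, 0, config$regression_noise_sd)
    out <- data.frame(year = 1988L + seq_len(n), wild_catch = wild_catch,
                      hijiki = hijiki, effort = effort, sst = sst, ph = ph)
    attr(out, "true_coefficients") <-
      stats::setNames(beta, c("(Intercept)", "hijiki", "effort", "sst", "ph"))
    class(out) <- c("TimeSeriesTable", "data.frame")
    out
  })
}
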