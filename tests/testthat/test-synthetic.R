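test_that("config validation rejects impossible study conditions", {
  expect_error(simConfig(target_fst = 1), "target_fst")
  expect_error(simConfig(mixture_proportions = c(0.5, 0.4)), "sum to 1")
  expect_error(simConfig(mixture_proportions = c(-0.1, 1.1)), "nonnegative")
  expect_error(simConfig(sample_sizes = 0), "sample_sizes")
  expect_error(simConfig(decay_rate = -1), "decay_rate")
})

test_that("generators are reproducible from the global seed", {
  cfg <- simConfig(seed = 7, n_populations = 3, sample_sizes = 20)
  f1 <- simulateBaselineFrequencies(cfg)
  f2 <- simulateBaselineFrequencies(cfg)
  expect_identical(f1, f2)
  g1 <- simulateGenotypes(f1, 20, seed = 7)
  g2 <- simulateGenotypes(f1, 20, seed = 7)
  expect_identical(g1@alleles, g2@alleles)
  expect_identical(simulateReleaseCohorts(cfg), simulateReleaseCohorts(cfg))
  expect_identical(simulateCatchCovariates(cfg), simulateCatchCovariates(cfg))
})

test_that("baseline frequencies are degenerate at F_ST = 0 and row-normalized", {
  cfg <- simConfig(seed = 3, n_populations = 5, target_fst = 0)
  fr <- simulateBaselineFrequencies(cfg)
  for (m in fr) {
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
    expect_true(all(abs(sweep(m, 2, m[1, ]) ) < 1e-12))  # all rows equal pbar
  }
  fr2 <- simulateBaselineFrequencies(simConfig(seed = 3, n_populations = 5,
                                               target_fst = 0.1))
  for (m in fr2) expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("island-model draws have mean pbar (binomial-Dirichlet moment check)", {
  cfg <- simConfig(seed = 11, n_populations = 1000, n_loci = 1,
                   alleles_per_locus = 2, target_fst = 0.05,
                   sample_sizes = rep(2L, 1000))
  fr <- simulateBaselineFrequencies(cfg, pbar = list(c(0.5, 0.5)))
  p <- fr[[1]][, 1]
  se <- stats::sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - 0.5), 3 * se + 1e-12)
})

test_that("island model reproduces the target F_ST under a Weir-Cockerham oracle", {
  reps <- 50
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- simConfig(seed = 1000 + r, n_populations = 20, n_loci = 5,
                     alleles_per_locus = 30, target_fst = 0.01,
                     sample_sizes = 50L)
    fr <- simulateBaselineFrequencies(cfg)
    gt <- simulateGenotypes(fr, 50, seed = 1000 + r)
    est[r] <- wcFst(gt)
  }
  mcse <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.01), 3 * mcse)
})

test_that("HWE genotype sampling: fixed locus, ploidy, heterozygote fraction", {
  # fixed locus -> all homozygous for that allele
  fr <- structure(list(locus01 = matrix(c(1, 0), 1, 2,
                                        dimnames = list("pop01", c("101", "102")))),
                  class = "BaselineFrequencies")
  gt <- simulateGenotypes(fr, 10, seed = 1)
  expect_true(all(gt@alleles == 101L))
  # ploidy conservation
  cfg <- simConfig(seed = 5, n_populations = 2, sample_sizes = 25)
  g2 <- simulateGenotypes(simulateBaselineFrequencies(cfg), 25, seed = 5)
  aft <- alleleCounts(g2)
  for (m in aft@counts) expect_equal(unname(rowSums(m)), rep(50, 2))
  # biallelic p = 0.5: heterozygote fraction ~ Binomial(n, 0.5)
  frb <- structure(list(l1 = matrix(0.5, 1, 2,
                                    dimnames = list("pop01", c("101", "102")))),
                   class = "BaselineFrequencies")
  gb <- simulateGenotypes(frb, 5000, seed = 2)
  het <- mean(gb@alleles[, 1, 1] != gb@alleles[, 1, 2])
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 5000))
  expect_error(simulateGenotypes(frb, 0), "positive")
})

test_that("mixture sampling honours the true proportions and edge cases", {
  cfg <- simConfig(seed = 9, n_populations = 2, sample_sizes = 60)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 60, seed = 9)
  # degenerate proportions
  m1 <- simulateMixture(gt, c(1, 0), 25, seed = 1)
  expect_true(all(m1$origin == sort(unique(gt@pop))[1]))
  # empty mixture allowed
  m0 <- simulateMixture(gt, c(0.5, 0.5), 0, seed = 1)
  expect_s4_class(m0$mixture, "GenotypeTable")
  expect_length(m0$mixture, 0)
  # origin counts within 3 binomial SE
  m2 <- simulateMixture(gt, c(0.4, 0.6), 10000, seed = 4)
  frac <- mean(m2$origin == sort(unique(gt@pop))[1])
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  expect_error(simulateMixture(gt, c(0.2, 0.3, 0.5), 10), "one proportion per")
})

test_that("release cohorts: noiseless log rates are exactly linear in year", {
  cfg <- simConfig(seed = 2, years = 25, decay_rate = 0.14, noise_sd = 0,
                   initial_recapture = 0.06)
  rc <- simulateReleaseCohorts(cfg)
  rate <- cumulativeRecaptureRate(rc, max_age = 8)$rate
  slope <- diff(log(rate))
  expect_equal(slope, rep(-0.14, 24), tolerance = 1e-10)
  expect_equal(rate[1], 0.06, tolerance = 1e-12)
  # lambda = 0, no noise: identical cohorts
  rc0 <- simulateReleaseCohorts(simConfig(seed = 2, years = 10, decay_rate = 0,
                                          noise_sd = 0))
  r0 <- cumulativeRecaptureRate(rc0, max_age = 8)$rate
  expect_equal(max(r0) - min(r0), 0, tolerance = 1e-15)
})

test_that("covariate series carries its exact linear signal when noiseless", {
  cfg <- simConfig(seed = 13, years = 27, regression_noise_sd = 0)
  tab <- simulateCatchCovariates(cfg)
  beta <- attr(tab, "true_coefficients")
  pred <- beta[1] + as.matrix(tab[, c("hijiki", "effort", "sst", "ph")]) %*% beta[-1]
  expect_equal(unname(tab$wild_catch), drop(pred), tolerance = 1e-10)
  fit <- suppressWarnings(   # summary.lm warns on an essentially perfect fit
    olsFit(tab$wild_catch, tab[, c("hijiki", "effort", "sst", "ph")]))
  expect_equal(fit$coefficients$Estimate, unname(beta), tolerance = 1e-6)
  expect_true(all(diff(tab$year) == 1))
})
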