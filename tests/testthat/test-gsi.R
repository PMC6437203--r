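test_that("diagnostic-allele mixture: proportions counted exactly, posteriors 0/1", {
  fx <- diagnosticFixture(nA = 12, n = 30, nBase = 500)
  est <- emEstimate(fx$mixture, fx$baselines, seed = 1)
  expect_equal(unname(mixingProportions(est)["srcA"]), 0.4, tolerance = 1e-5)
  post <- assignIndividuals(est)
  expect_true(all(post$map_source[1:12] == "srcA"))
  expect_true(all(post$srcA[1:12] > 0.999))
  expect_true(all(rowSums(est@posteriors) - 1 < 1e-9))
  # information SE equals the binomial SE of the reduced problem
  expect_equal(unname(standardErrors(est, "mixture")["srcA"]),
               sqrt(0.4 * 0.6 / 30), tolerance = 1e-3)
})

test_that("EM equals a 0.001-step grid search on small 2-source problems", {
  for (s in 1:8) {
    cfg <- simConfig(seed = 100 + s, n_populations = 2, target_fst = 0.08,
                     sample_sizes = 40,
                     mixture_proportions = c(0.3, 0.7))
    gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 40, seed = 100 + s)
    n <- sample(5:20, 1)
    mix <- simulateMixture(gt, c(0.3, 0.7), n, seed = s)
    aft <- alleleCounts(gt)
    est <- emEstimate(mix$mixture, aft, seed = s)
    logf <- HatcheryImpact:::gsiLogLikMatrix(mix$mixture, aft)
    expect_lt(abs(mixingProportions(est)[1] - gridSearchPi(logf)), 0.005)
  }
})

test_that("EM log-likelihood is invariant to locus reordering", {
  cfg <- simConfig(seed = 61, n_populations = 2, sample_sizes = 50)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 50, seed = 61)
  mix <- simulateMixture(gt, c(0.4, 0.6), 40, seed = 2)
  aft <- alleleCounts(gt)
  e1 <- emEstimate(mix$mixture, aft, seed = 3)
  ord <- c(4, 2, 5, 1, 3)
  gt2 <- genotypeTable(mix$mixture@ids, mix$mixture@pop,
                       mix$mixture@alleles[, ord, , drop = FALSE],
                       mix$mixture@loci[ord])
  e2 <- emEstimate(gt2, aft, seed = 3)
  expect_equal(mixingProportions(e1), mixingProportions(e2), tolerance = 1e-6)
  expect_equal(e1@logLik, e2@logLik, tolerance = 1e-8)
})

test_that("single-source degenerate case returns pi = 1", {
  cfg <- simConfig(seed = 63, n_populations = 1, sample_sizes = 30,
                   mixture_proportions = 1)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 30, seed = 63)
  mix <- simulateMixture(gt, 1, 10, seed = 1)
  est <- emEstimate(mix$mixture, alleleCounts(gt))
  expect_equal(unname(mixingProportions(est)), 1)
})

test_that("uniform source likelihoods give posteriors equal to pi-hat", {
  # individuals typed at no locus carry no information
  arr <- array(NA_integer_, dim = c(6, 1, 2))
  mix <- genotypeTable(sprintf("m%d", 1:6), "mix", arr, "loc1")
  fx <- diagnosticFixture(nA = 5, n = 10, nBase = 50)
  est <- suppressWarnings(emEstimate(mix, fx$baselines, seed = 1))
  post <- est@posteriors
  for (i in seq_len(nrow(post)))
    expect_equal(unname(post[i, ]), unname(mixingProportions(est)),
                 tolerance = 1e-6)
})

test_that("baseline-aware SE: infinite baselines leave only the mixture component", {
  fx <- diagnosticFixture(nA = 12, n = 30, nBase = 50)
  big <- fx$baselines
  for (l in seq_along(big@counts)) big@counts[[l]] <- big@counts[[l]] * 1e6L
  est <- emEstimate(fx$mixture, big, seed = 1)
  est <- baselineAwareSE(est, fx$mixture, big, n_resample = 50, seed = 1)
  expect_lt(max(standardErrors(est, "baseline")), 1e-3)
  expect_equal(standardErrors(est, "total"), standardErrors(est, "mixture"),
               tolerance = 1e-3)
  # finite baselines add a strictly positive component
  est2 <- emEstimate(fx$mixture, fx$baselines, seed = 1)
  est2 <- baselineAwareSE(est2, fx$mixture, fx$baselines, n_resample = 50, seed = 1)
  expect_true(all(standardErrors(est2, "total") >=
                    standardErrors(est2, "mixture") - 1e-12))
})

test_that("bootstrap CI covers the point estimate and shrinks with n", {
  cfg <- simConfig(seed = 67, n_populations = 2, target_fst = 0.08,
                   sample_sizes = 60)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 60, seed = 67)
  aft <- alleleCounts(gt)
  mixS <- simulateMixture(gt, c(0.4, 0.6), 50, seed = 5)
  mixL <- simulateMixture(gt, c(0.4, 0.6), 200, seed = 5)
  estS <- emEstimate(mixS$mixture, aft, seed = 1)
  ciS <- bootstrapCI(mixS$mixture, aft, n_boot = 99, seed = 2)
  expect_true(all(mixingProportions(estS) >= ciS[, "lower"] - 1e-9 &
                    mixingProportions(estS) <= ciS[, "upper"] + 1e-9))
  ciL <- bootstrapCI(mixL$mixture, aft, n_boot = 99, seed = 2)
  widthS <- ciS[1, 2] - ciS[1, 1]
  widthL <- ciL[1, 2] - ciL[1, 1]
  expect_lt(widthL, widthS)  # 4x the mixture size must narrow the interval
})
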