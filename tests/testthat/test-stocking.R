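test_that("hatchery-fraction expansion follows the mark-survey arithmetic", {
  r <- estimateHatcheryFraction(100, 0)
  expect_equal(r$P_h, 0); expect_equal(r$se, 0)
  r <- estimateHatcheryFraction(100, 50, q = 1)
  expect_equal(r$P_h, 0.5); expect_equal(r$se, 0.05)
  r <- estimateHatcheryFraction(100, 45, q = 0.9)
  expect_equal(r$P_h, 0.5, tolerance = 1e-12)
  expect_error(estimateHatcheryFraction(100, 10, q = 0), "q must")
  expect_error(estimateHatcheryFraction(10, 11), "exceed")
  # pooling by landings weights
  ph <- estimateHatcheryFraction(c(100, 100), c(80, 20),
                                 stratum = c("inner", "outer"))
  pool <- poolHatcheryFraction(ph, weights = c(3, 1))
  expect_equal(pool$P_h, 0.65)
})

test_that("catch expansion conserves landed mass and splits by P_h", {
  w <- c(age1 = 0.5, age2 = 2)
  comp <- c(0.25, 0.75)
  out <- expandCatch(100, P_h = 0.3, w, comp)
  expect_equal(sum(out$mass_hatchery + out$mass_wild), 100)
  expect_equal(out$numbers_total, c(100 * 0.25 / 0.5, 100 * 0.75 / 2))
  out0 <- expandCatch(50, 0, w, comp)
  expect_equal(sum(out0$mass_hatchery), 0)
  expect_equal(sum(out0$mass_wild), 50)
  expect_error(expandCatch(10, 0.5, w, c(0.5, 0.6)), "sum to 1")
  expect_error(expandCatch(10, 0.5, w, c(0.5)), "align")
})

test_that("effort correction of cumulative recapture rates", {
  cohorts <- structure(list(
    cohorts = data.frame(release_year = 1, n_released = 1000),
    recaptures = matrix(c(50, 30, 20, 0, 0, 0, 0, 0), 1,
                        dimnames = list(1, paste0("age", 1:8))),
    effort = data.frame(year = 1:9, effort = rep(2, 9)),
    weight_by_age = rep(1, 8)), class = "ReleaseCohortSeries")
  r <- cumulativeRecaptureRate(cohorts, max_age = 3)
  expect_equal(r$rate, 0.10)      # flat effort: corrected = uncorrected
  expect_equal(cumulativeRecaptureRate(cohorts, max_age = 3,
                                       corrected = FALSE)$rate, 0.10)
  expect_equal(cumulativeRecaptureRate(cohorts, max_age = 1)$rate, 0.05)
  # halving effort in a recapture year doubles that year's contribution
  cohorts$effort$effort[3] <- 1   # age-2 recapture year
  r2 <- cumulativeRecaptureRate(cohorts, max_age = 3)
  expect_equal(r2$rate, (50 + 60 + 20) / 1000)
  cohorts$effort$effort[3] <- 0
  expect_error(cumulativeRecaptureRate(cohorts, max_age = 3), "effort")
})

test_that("exponential decay fit recovers exact data to high precision", {
  x <- 0:20
  y <- 2 * exp(-0.1 * x)
  fit <- fitExponentialDecay(x, y)
  expect_equal(fit@amplitude, 2, tolerance = 1e-8)
  expect_equal(decayRate(fit), 0.1, tolerance = 1e-8)
  expect_equal(fit@method, "nls")
  # flat data: rate indistinguishable from zero
  set.seed(3)
  yflat <- exp(stats::rnorm(21, 0, 0.05))
  f0 <- fitExponentialDecay(x, yflat)
  expect_lt(abs(decayRate(f0)), 3 * decayRate(f0, se = TRUE))
  expect_gt(f0@pValue, 0.1)
  expect_error(fitExponentialDecay(1:2, c(1, 2)), ">= 3")
  expect_error(fitExponentialDecay(1:3, c(1, -1, 2)), "positive")
})

test_that("decline-rate comparison: z, one-sided p, and combined rates", {
  f <- fitExponentialDecay(0:10, 3 * exp(-0.2 * (0:10)))
  same <- compareDecayRates(f, f)
  expect_equal(same$z, 0)
  expect_equal(same$p, 0.5)
  r <- compareDecayRates(c(0.1222, 0.018), c(0.1565, 0.017))
  expect_equal(r$average, 0.13935, tolerance = 1e-12)
  expect_lt(abs(stats::pnorm(1.404, lower.tail = FALSE) - 0.0801), 1e-4)
})

test_that("fitness conversion 1 - exp(-lambda G) and its error conventions", {
  r <- fitnessReductionPerGeneration(0.1391, 4.8, 0.0123)
  expect_equal(unname(r["reduction"]), 0.487, tolerance = 5e-4)
  expect_equal(unname(r["se"]), 0.059, tolerance = 1e-3)
  expect_equal(unname(r["se_delta"]),
               4.8 * exp(-0.1391 * 4.8) * 0.0123, tolerance = 1e-12)
  expect_equal(unname(fitnessReductionPerGeneration(0, 5)["reduction"]), 0)
  expect_equal(unname(fitnessReductionPerGeneration(log(2), 1)["reduction"]),
               0.5, tolerance = 1e-12)
  expect_error(fitnessReductionPerGeneration(0.1, 0), "positive")
})

test_that("replacement recursion: neutral closed form and absorbing states", {
  # f = 1: p_{t+1} = p_t / (1 + R) exactly, for 100 generations
  state <- c(WW = 1, WH = 0, HH = 0)
  p <- 1
  for (t in 1:100) {
    state <- replacementStep(state, f = 1, R = 0.1)
    p <- p / 1.1
    expect_equal(state[["WW"]] + state[["WH"]] / 2, p, tolerance = 1e-12)
    expect_simplex(state)
  }
  # R = 0, f = 1: state unchanged after HWE re-equilibration
  s0 <- c(WW = 0.25, WH = 0.5, HH = 0.25)
  expect_equal(replacementStep(s0, 1, 0), s0, tolerance = 1e-12)
  # p = 0 absorbing for all (f, R)
  for (f in c(0, 0.5, 1)) for (R in c(0, 0.3)) {
    s <- replacementStep(c(WW = 0, WH = 0, HH = 1), f, R)
    expect_equal(s[["WW"]] + s[["WH"]] / 2, 0)
  }
  expect_warning(replacementStep(s0, 1.2, 0.1), "f > 1")
})

test_that("generations to threshold match the closed form and persistence logic", {
  expect_equal(generationsToThreshold(1, 0.1, 0.5), 8)
  expect_equal(generationsToThreshold(1, 0.1, 0.01), 49)
  expect_equal(generationsToThreshold(1, 0.1, 0.01),
               ceiling(log(0.01) / log(1 / 1.1)))
  # f = 0.6, R = 0.3: persistence condition (1+f)/(2f(1+R)) = 1.026 > 1
  expect_identical(generationsToThreshold(0.6, 0.3, 0.01), Inf)
  tr <- replacementTrajectory(0.6, 0.3, max_generations = 1e5)
  expect_gt(tr@equilibrium, 0.01)
  expect_true(tr@converged)
})

test_that("equilibrium surface: no stocking keeps the wild gene fixed; monotone in R", {
  surf <- equilibriumSurface(f_grid = c(0, 0.4, 0.8, 1),
                             R_grid = c(0, 0.2, 0.4, 0.8),
                             max_generations = 2e5)
  expect_true(all(surf$equilibrium[, "R=0"] == 1))
  for (i in seq_len(nrow(surf$equilibrium)))
    expect_true(all(diff(surf$equilibrium[i, ]) <= 1e-9))
  expect_true(all(surf$equilibrium >= 0 & surf$equilibrium <= 1))
})

test_that("persistence boundary predicts never vs finite replacement on a grid", {
  fs <- seq(0.1, 1, length.out = 7)
  Rs <- seq(0.05, 0.9, length.out = 7)
  for (f in fs) for (R in Rs) {
    persists <- (1 + f) / (2 * f * (1 + R)) > 1
    g <- generationsToThreshold(f, R, 0.01, max_generations = 2e5)
    if (persists) expect_identical(g, Inf)
    else expect_true(is.finite(g))
  }
})

test_that("trajectory object: simplex invariant and accessors", {
  tr <- replacementTrajectory(0.8, 0.2, max_generations = 5000)
  expect_s4_class(tr, "ReplacementTrajectory")
  expect_true(all(abs(rowSums(tr@states) - 1) < 1e-9))
  p <- wildGeneProportion(tr)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) <= 1e-12))  # monotone decline under stocking
})
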