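#' Estimate the hatchery fraction of landings from a mark survey
#'
#' Landed fish are screened for a hatchery mark (e.g. deformity of the
#' internostril epidermis); the raw mark fraction is expanded by the mark
#' incidence \code{q} among hatchery fish:
#' \code{P_h = (n_marked/n_checked)/q}, clamped to [0, 1], with
#' \code{SE = sqrt(phat (1 - phat)/n_checked)/q} on the raw fraction.
#'
#' @param n_checked fish examined (vectorized over strata).
#' @param n_marked marked fish found.
#' @param q mark incidence among hatchery fish, in (0, 1]; default 1
#'   (a fully penetrant mark).
#' @param stratum optional stratum labels (area, year, market).
#' @return data.frame with columns stratum, n_checked, n_marked, q,
#'   P_h, se.
#' @export
estimateHatcheryFraction <- function(n_checked, n_marked, q = 1,
                                     stratum = NULL) {
  if (any(q <= 0) || any(q > 1)) stop("mark incidence q must lie in (0, 1]")
  if (any(n_checked < 1)) stop("n_checked must be >= 1")
  if (any(n_marked > n_checked)) stop("n_marked cannot exceed n_checked")
  q <- rep_len(q, length(n_checked))
  phat <- n_marked / n_checked
  data.frame(stratum = stratum %||% as.character(seq_along(n_checked)),
             n_checked = n_checked, n_marked = n_marked, q = q,
             P_h = pmin(phat / q, 1),
             se = sqrt(phat * (1 - phat) / n_checked) / q)
}

#' Pool stratified hatchery fractions by landings weights
#'
#' @param ph data.frame from \link{estimateHatcheryFraction}.
#' @param weights landings per stratum (tonnes); weighted average.
#' @return list with \code{P_h} and \code{se}
#'   (\code{sqrt(sum(w^2 se^2))/sum(w)}).
#' @export
poolHatcheryFraction <- function(ph, weights) {
  stopifnot(nrow(ph) == length(weights), all(weights >= 0))
  w <- weights / sum(weights)
  list(P_h = sum(w * ph$P_h), se = sqrt(sum(w^2 * ph$se^2)))
}

#' Expand total landings into hatchery/wild numbers and mass at age
#'
#' Landed mass is allocated to age classes by the age composition, converted
#' to numbers through the age-weight key, and split by the hatchery
#' fraction. Total landed mass is conserved.
#'
#' @param landings_total total landed mass (tonnes).
#' @param P_h hatchery fraction of the landings.
#' @param weight_by_age named mean body weight per age class (kg).
#' @param age_composition proportions of landed mass per age class
#'   (same length/order as \code{weight_by_age}, summing to 1).
#' @return data.frame per age class: mass and numbers (thousands of fish
#'   when mass is in tonnes and weight in kg), each split hatchery/wild.
#' @export
expandCatch <- function(landings_total, P_h, weight_by_age, age_composition) {
  if (length(weight_by_age) != length(age_composition))
    stop("weight_by_age and age_composition must align")
  if (abs(sum(age_composition) - 1) > 1e-8)
    stop("age_composition must sum to 1")
  if (any(weight_by_age <= 0)) stop("weights must be positive")
  if (P_h < 0 || P_h > 1) stop("P_h must be a proportion")
  mass <- landings_total * age_composition
  numbers <- mass / weight_by_age
  data.frame(age = names(weight_by_age) %||% seq_along(weight_by_age),
             weight = weight_by_age,
             mass_total = mass,
             mass_hatchery = mass * P_h,
             mass_wild = mass * (1 - P_h),
             numbers_total = numbers,
             numbers_hatchery = numbers * P_h,
             numbers_wild = numbers * (1 - P_h),
             row.names = NULL)
}

#' Effort-corrected cumulative recapture rate per release cohort
#'
#' \code{rate = sum_(age <= max_age) recaptures(age) (E_ref/E_year(age)) /
#' n_released}; the effort correction standardizes each recapture year's
#' contribution to a reference fishing-effort level.
#'
#' @param cohorts a \code{"ReleaseCohortSeries"} (see
#'   \link{simulateReleaseCohorts} for the layout).
#' @param max_age include recaptures up to this age (1-8).
#' @param effort_reference_year calendar year whose effort is the
#'   standard; default the first year of the effort series.
#' @param corrected logical; \code{FALSE} gives the raw rate.
#' @return data.frame: release_year, rate.
#' @export
cumulativeRecaptureRate <- function(cohorts, max_age = 8L,
                                    effort_reference_year = NULL,
                                    corrected = TRUE) {
  stopifnot(inherits(cohorts, "ReleaseCohortSeries"),
            max_age %in% 1:8)
  eff <- cohorts$effort
  refYear <- effort_reference_year %||% eff$year[1]
  eRef <- eff$effort[match(refYear, eff$year)]
  if (is.na(eRef) || eRef <= 0) stop("invalid effort reference year")
  ages <- seq_len(max_age)
  rate <- numeric(nrow(cohorts$cohorts))
  for (y in seq_along(rate)) {
    cal <- cohorts$cohorts$release_year[y] + ages
    e <- eff$effort[match(cal, eff$year)]
    if (corrected && (any(is.na(e)) || any(e <= 0)))
      stop("zero or missing effort in a needed recapture year (cohort ",
           cohorts$cohorts$release_year[y], ")")
    corr <- if (corrected) eRef / e else 1
    rate[y] <- sum(cohorts$recaptures[y, ages] * corr) /
      cohorts$cohorts$n_released[y]
  }
  data.frame(release_year = cohorts$cohorts$release_year, rate = rate)
}

#' Fit an exponential decline y = a exp(-lambda x)
#'
#' The default fits nonlinear least squares on the original scale,
#' initialized from the log-linear OLS fit, falling back to the log-linear
#' fit (flagged) if the optimizer fails. \code{method = "loglinear"}
#' requests the log-scale OLS fit directly; under multiplicative
#' (lognormal) rate noise that variant is the exactly matched model, so
#' its rate intervals are the calibrated ones. The t statistic and
#' two-sided p-value test lambda != 0 with df = n - 2.
#'
#' @param x predictor (years).
#' @param y positive response (rates).
#' @param method "nls" (original-scale nonlinear least squares) or
#'   "loglinear" (OLS on log rates).
#' @return A \linkS4class{DecayFit}.
#' @export
fitExponentialDecay <- function(x, y, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  if (length(x) < 3 || length(x) != length(y)) stop("need >= 3 (x, y) points")
  if (any(y <= 0)) stop("rates must be positive for the log-linear stage")
  ll <- stats::lm(log(y) ~ x)
  a0 <- unname(exp(coef(ll)[1])); l0 <- unname(-coef(ll)[2])
  df <- length(x) - 2
  fit <- if (method == "nls") tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-lambda * x),
                      start = list(a = a0, lambda = l0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL) else NULL
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    tstat <- cf["lambda", "Estimate"] / cf["lambda", "Std. Error"]
    return(new("DecayFit",
               amplitude = cf["a", "Estimate"], rate = cf["lambda", "Estimate"],
               seAmplitude = cf["a", "Std. Error"],
               seRate = cf["lambda", "Std. Error"],
               tStat = tstat,
               pValue = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
               df = df, fitted = as.numeric(stats::fitted(fit)),
               residuals = as.numeric(stats::resid(fit)),
               method = "nls", converged = TRUE))
  }
  # log-linear path: delta-method SE for the amplitude
  cf <- summary(ll)$coefficients
  tstat <- -cf[2, 1] / cf[2, 2]
  new("DecayFit",
      amplitude = as.numeric(a0), rate = as.numeric(l0),
      seAmplitude = as.numeric(a0 * cf[1, 2]), seRate = cf[2, 2],
      tStat = tstat,
      pValue = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
      df = df, fitted = as.numeric(a0 * exp(-l0 * x)),
      residuals = as.numeric(y - a0 * exp(-l0 * x)),
      method = "loglinear", converged = method == "loglinear")
}

#' Compare two exponential decline rates
#'
#' \code{z = |lambda_A - lambda_B| / sqrt(SE_A^2 + SE_B^2)} with a
#' one-sided normal p-value, plus the simple-average and inverse-variance
#' pooled combined rates with standard errors.
#'
#' @param fitA,fitB \linkS4class{DecayFit} objects, or numeric
#'   \code{c(rate, se)} pairs.
#' @return list: z, p (one-sided), average, se_average, pooled, se_pooled.
#' @export
compareDecayRates <- function(fitA, fitB) {
  get <- function(f) {
    if (is(f, "DecayFit")) c(f@rate, f@seRate)
    else if (is.numeric(f) && length(f) == 2) f
    else stop("supply a DecayFit or c(rate, se)")
  }
  a <- get(fitA); b <- get(fitB)
  sed <- sqrt(a[2]^2 + b[2]^2)
  z <- if (a[1] == b[1]) 0 else abs(a[1] - b[1]) / sed
  w <- if (a[2] == 0 && b[2] == 0) c(1, 1) else 1 / c(a[2]^2, b[2]^2)
  list(z = z,
       p = stats::pnorm(z, lower.tail = FALSE),
       average = mean(c(a[1], b[1])),
       se_average = sed / 2,
       pooled = sum(w * c(a[1], b[1])) / sum(w),
       se_pooled = sqrt(1 / sum(w)))
}

#' Per-generation fitness (survival) reduction from a per-year decline rate
#'
#' \code{1 - exp(-lambda G)} for generation time \code{G} years. Two error
#' conventions are reported: \code{se}, the first-order SE of the
#' per-generation decay exponent \code{lambda G} (i.e. \code{G SE_lambda},
#' the convention used in field reports of per-generation loss), and
#' \code{se_delta}, the full delta-method SE of the transformed quantity,
#' \code{G exp(-lambda G) SE_lambda}.
#'
#' @param lambda per-year exponential decline rate.
#' @param G generation time in years (> 0).
#' @param se_lambda optional SE of \code{lambda}.
#' @return named vector: reduction, se, se_delta (SEs are NA when
#'   \code{se_lambda} is missing).
#' @export
fitnessReductionPerGeneration <- function(lambda, G, se_lambda = NA_real_) {
  if (G <= 0) stop("generation time must be positive")
  c(reduction = 1 - exp(-lambda * G),
    se = G * se_lambda,
    se_delta = G * exp(-lambda * G) * se_lambda)
}

#' One generation of the wild-gene replacement recursion
#'
#' Semelparous population with genotypes WW (wild), WH, HH (hatchery) at
#' one locus. Each generation: (1) reproduction weighted by fitness 1,
#' (1+f)/2 and f respectively; (2) gametes unite at random, so wild-born
#' offspring are at Hardy-Weinberg proportions in the weighted W-gamete
#' frequency; (3) stocked HH recruits are added at \code{R} per wild-born
#' recruit.
#'
#' @param state numeric length-3 vector of genotype proportions
#'   (WW, WH, HH), summing to 1.
#' @param f fitness of the hatchery genotype HH (wild = 1). Values in
#'   [0, 1] are the study regime; f > 1 is allowed with a warning.
#' @param R stocking rate: stocked HH recruits per wild-born recruit (>= 0).
#' @return next generation's genotype proportions (WW, WH, HH).
#' @export
replacementStep <- function(state, f, R) {
  stopifnot(length(state) == 3, all(state >= -1e-12),
            abs(sum(state) - 1) < 1e-9)
  if (f < 0 || R < 0) stop("f and R must be nonnegative")
  if (f > 1) warning("hatchery fitness f > 1 is outside the study regime")
  w <- c(1, (1 + f) / 2, f)
  wt <- state * w
  if (sum(wt) == 0) return(c(WW = 0, WH = 0, HH = 1))  # no reproduction: only stocked fish
  wt <- wt / sum(wt)
  p <- wt[1] + wt[2] / 2                  # W-gamete frequency after selection
  offspring <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  nextState <- (offspring + c(0, 0, R)) / (1 + R)
  stats::setNames(nextState, c("WW", "WH", "HH"))
}

#' Iterate the replacement recursion to (or towards) equilibrium
#'
#' @param f,R see \link{replacementStep}.
#' @param p0 initial wild-gene proportion (default 1, a pristine wild
#'   population at Hardy-Weinberg).
#' @param max_generations iteration cap (the full trajectory is stored;
#'   use \link{equilibriumSurface} for long-run equilibria only).
#' @param tol convergence tolerance on the genotype proportions.
#' @return A \linkS4class{ReplacementTrajectory}.
#' @export
replacementTrajectory <- function(f, R, p0 = 1, max_generations = 10000,
                                  tol = 1e-12) {
  stopifnot(p0 >= 0, p0 <= 1)
  state <- c(WW = p0^2, WH = 2 * p0 * (1 - p0), HH = (1 - p0)^2)
  states <- list(state)
  p <- p0
  converged <- FALSE
  for (t in seq_len(max_generations)) {
    nxt <- replacementStep(state, f, R)
    delta <- max(abs(nxt - state))
    state <- nxt
    states[[t + 1L]] <- state
    p <- c(p, state[["WW"]] + state[["WH"]] / 2)
    if (delta < tol) { converged <- TRUE; break }
  }
  m <- do.call(rbind, states)
  rownames(m) <- NULL
  new("ReplacementTrajectory", states = m, wildGene = unname(p),
      equilibrium = unname(tail(p, 1)), converged = converged,
      f = f, R = R)
}

#' First generation at which the wild-gene proportion falls below a threshold
#'
#' Starting from a pristine wild population (p0 = 1), iterates the
#' recursion and returns the smallest generation t with p_t < threshold
#' (strict), or \code{Inf} ("never") when the trajectory converges to an
#' equilibrium at or above the threshold. An interior equilibrium exists
#' exactly when the persistence condition \code{(1 + f)/(2 f (1 + R)) > 1}
#' holds (W gametes out-reproduce their dilution at low frequency).
#'
#' @param f,R see \link{replacementStep}.
#' @param threshold wild-gene proportion in (0, 1).
#' @param max_generations iteration cap.
#' @return integer generation, or \code{Inf} when the wild gene persists
#'   above the threshold.
#' @export
generationsToThreshold <- function(f, R, threshold, max_generations = 1e6) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  state <- c(WW = 1, WH = 0, HH = 0)
  p <- 1
  for (t in seq_len(max_generations)) {
    state <- replacementStep(state, f, R)
    pNew <- state[["WW"]] + state[["WH"]] / 2
    if (pNew < threshold) return(t)
    if (abs(pNew - p) < 1e-15) return(Inf)  # settled at/above the threshold
    p <- pNew
  }
  Inf
}

#' Equilibrium wild-gene proportion over a fitness x stocking-rate grid
#'
#' @param f_grid hatchery fitness values in [0, 1].
#' @param R_grid stocking rates (>= 0).
#' @param max_generations,tol iteration controls per cell.
#' @return list: \code{equilibrium} (matrix f x R of equilibrium wild-gene
#'   proportions) and \code{converged} (logical matrix).
#' @export
equilibriumSurface <- function(f_grid, R_grid, max_generations = 1e6,
                               tol = 1e-12) {
  iterate <- function(f, R) {
    state <- c(1, 0, 0)
    for (t in seq_len(max_generations)) {
      nxt <- replacementStep(state, f, R)
      delta <- max(abs(nxt - state))
      state <- nxt
      if (delta < tol)
        return(list(p = state[[1]] + state[[2]] / 2, converged = TRUE))
    }
    list(p = state[[1]] + state[[2]] / 2, converged = FALSE)
  }
  eq <- matrix(NA_real_, length(f_grid), length(R_grid),
               dimnames = list(paste0("f=", f_grid), paste0("R=", R_grid)))
  conv <- eq == 0
  for (i in seq_along(f_grid))
    for (j in seq_along(R_grid)) {
      r <- iterate(f_grid[i], R_grid[j])
      eq[i, j] <- r$p
      conv[i, j] <- r$converged
    }
  list(equilibrium = eq, converged = conv)
}
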