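#' Run the full synthetic end-to-end monitoring demo
#'
#' Generates synthetic genotypes, a mixture sample, release cohorts and a
#' covariate series; runs diversity statistics, empirical Bayes F_ST with a
#' UPGMA dendrogram, genetic stock identification, decay/fitness analysis,
#' the replacement-recursion grid and the stepwise regression; writes a
#' plain-text report comparing estimates to generator truth, the Genepop /
#' CSV / Newick outputs, and a run manifest. Deterministic: the same seed
#' reproduces byte-identical numeric output.
#'
#' @param seed integer global seed.
#' @param dir output directory (created if needed).
#' @param config optional \link{simConfig}; by default one is built from
#'   \code{seed} with four baseline populations.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage's result and the manifest.
#' @export
runDemo <- function(seed = 1L, dir = tempfile("demo"), config = NULL,
                    quiet = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  cfg <- config %||% simConfig(seed = seed, n_populations = 4L,
                               sample_sizes = 80L, years = 27L)
  stage <- "simulate"
  res <- tryCatch({
    say("stage: simulate")
    freqs <- simulateBaselineFrequencies(cfg)
    gt <- simulateGenotypes(freqs, cfg$sample_sizes, seed = cfg$seed)
    writeGenepop(gt, file.path(dir, "baselines.gen"))
    twoPops <- gt[gt@pop %in% sort(unique(gt@pop))[1:2]]
    mix <- simulateMixture(twoPops, cfg$mixture_proportions,
                           n = 167L, seed = cfg$seed)
    cohorts <- simulateReleaseCohorts(cfg)
    covars <- simulateCatchCovariates(cfg)
    utils::write.csv(covars, file.path(dir, "covariates.csv"),
                     row.names = FALSE)

    stage <- "diversity"
    say("stage: diversity")
    div <- diversityReport(gt)
    utils::write.csv(div, file.path(dir, "diversity.csv"), row.names = FALSE)

    stage <- "ebfst"
    say("stage: ebfst")
    eb <- ebFst(alleleCounts(gt))
    tree <- upgmaTree(eb$fst)
    writeNewick(tree, file.path(dir, "ebfst_upgma.nwk"))

    stage <- "gsi"
    say("stage: gsi")
    est <- emEstimate(mix$mixture, alleleCounts(twoPops), seed = cfg$seed)
    est <- baselineAwareSE(est, mix$mixture, alleleCounts(twoPops),
                           n_resample = 100L, seed = cfg$seed)
    truePi <- stats::setNames(cfg$mixture_proportions,
                              sort(unique(twoPops@pop)))

    stage <- "decay"
    say("stage: decay")
    rates <- cumulativeRecaptureRate(cohorts, max_age = 8L)
    decay <- fitExponentialDecay(rates$release_year - 1, rates$rate)
    fitness <- fitnessReductionPerGeneration(decay@rate, 4.8, decay@seRate)

    stage <- "replace"
    say("stage: replace")
    grid <- equilibriumSurface(seq(0, 1, by = 0.2), seq(0, 1, by = 0.2))
    gens <- c(half = generationsToThreshold(1, 0.1, 0.5),
              one_percent = generationsToThreshold(1, 0.1, 0.01))

    stage <- "regress"
    say("stage: regress")
    reg <- stepwiseAIC(covars$wild_catch,
                       covars[, c("hijiki", "effort", "sst", "ph")])

    list(config = cfg, genotypes = gt, mixture = mix, diversity = div,
         ebfst = eb, tree = tree, gsi = est, true_pi = truePi,
         cohorts = cohorts, recapture_rates = rates, decay = decay,
         fitness = fitness, equilibrium = grid, generations = gens,
         regression = reg)
  }, error = function(e) {
    stop("demo failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  reportPath <- file.path(dir, "report.txt")
  con <- file(reportPath, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("HatcheryImpact synthetic demo (seed %d)", cfg$seed)
  w("== diversity ==")
  for (i in seq_len(nrow(res$diversity)))
    w("  %s: allelic richness %.3f (g = %d), He %.3f",
      res$diversity$population[i], res$diversity$allelic_richness[i],
      res$diversity$rarefaction_g[i], res$diversity$expected_heterozygosity[i])
  w("== empirical Bayes F_ST ==")
  w("  mean pairwise %.5f +/- %.5f (s.d.); target %.3f",
    res$ebfst$mean, res$ebfst$sd, cfg$target_fst)
  w("== genetic stock identification ==")
  for (k in names(res$true_pi))
    w("  %s: estimate %.3f +/- %.3f (truth %.3f)", k,
      mixingProportions(res$gsi)[k], standardErrors(res$gsi)[k],
      res$true_pi[k])
  w("== recapture decline ==")
  w("  fitted rate %.4f +/- %.4f per year (truth %.3f); per-generation loss %.3f",
    res$decay@rate, res$decay@seRate, cfg$decay_rate,
    res$fitness[["reduction"]])
  w("== replacement recursion ==")
  w("  f=1, R=0.1: wild gene < 50%% at generation %d, < 1%% at generation %d",
    res$generations[["half"]], res$generations[["one_percent"]])
  w("== regression ==")
  w("  selected: %s (R^2 = %.3f, AIC %.2f vs full %.2f)",
    paste(res$regression$selected, collapse = ", "),
    res$regression$r_squared, res$regression$aic, res$regression$aic_full)
  close(con)

  outputs <- c("baselines.gen", "covariates.csv", "diversity.csv",
               "ebfst_upgma.nwk", "report.txt")
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("HatcheryImpact"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %s", configHash(cfg)),
    "stages: simulate diversity ebfst gsi decay replace regress",
    paste0("output: ", outputs, " md5=",
           tools::md5sum(file.path(dir, outputs))))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  res$manifest <- manifest
  say("demo complete: ", reportPath)
  invisible(res)
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a single named pipeline stage
#'
#' Thin dispatcher over the package's stage functions, for scripted runs.
#' Parameters are passed as a named list and echoed.
#'
#' @param name stage name: one of "simulate", "diversity", "ebfst", "gsi",
#'   "ph", "recapture", "decay", "replace", "regress", "demo".
#' @param config named list of arguments for the stage function.
#' @param quiet suppress the parameter echo.
#' @return the stage's result.
#' @export
runStage <- function(name, config = list(), quiet = FALSE) {
  stages <- list(
    simulate  = function(cfg) {
      sc <- do.call(simConfig, cfg)
      freqs <- simulateBaselineFrequencies(sc)
      simulateGenotypes(freqs, sc$sample_sizes, seed = sc$seed)
    },
    diversity = function(cfg) do.call(diversityReport, cfg),
    ebfst     = function(cfg) do.call(ebFst, cfg),
    gsi       = function(cfg) do.call(emEstimate, cfg),
    ph        = function(cfg) do.call(estimateHatcheryFraction, cfg),
    recapture = function(cfg) do.call(cumulativeRecaptureRate, cfg),
    decay     = function(cfg) do.call(fitExponentialDecay, cfg),
    replace   = function(cfg) {
      thresholds <- cfg$thresholds %||% c(0.5, 0.01)
      data.frame(threshold = thresholds,
                 generations = vapply(thresholds, function(th)
                   generationsToThreshold(cfg$f, cfg$R, th), 0))
    },
    regress   = function(cfg) do.call(stepwiseAIC, cfg),
    demo      = function(cfg) do.call(runDemo, cfg))
  if (!name %in% names(stages))
    stop("unknown stage '", name, "'; valid stages: ",
         paste(names(stages), collapse = ", "))
  if (!quiet)
    message("stage ", name, " (",
            paste(names(config), collapse = ", "), ")")
  stages[[name]](config)
}
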