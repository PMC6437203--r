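# HatcheryImpact

Quantifying what a hatchery release program does to the wild population it
is meant to support.

Marine stock-enhancement programs release millions of captively bred
juveniles into fished populations. Two questions decide whether such a
program helps or harms: *how much of the catch and of the gene pool is
hatchery-derived*, and *what happens to wild genes and hatchery fitness
over generations of continued stocking*. `HatcheryImpact` implements the
computational core of a long-term monitoring analysis for a semi-closed
bay population of red sea bream (*Pagrus major*), in a form reusable for
any program with mark surveys, release-cohort recapture records,
microsatellite/mtDNA baselines and catch-effort series.

The package is for fisheries and conservation-genetics analysts: it takes
Genepop genotype files, aligned FASTA haplotypes and CSV catch tables, and
produces the program-evaluation statistics below.

## What it computes

**Genetic stock identification (GSI).** Conditional-maximum-likelihood
mixture estimation: the mixed sample's likelihood
`L(π) = Π_i Σ_k π_k f_k(x_i)` is maximized by EM with baseline allele
frequencies held at their (smoothed) sample estimates; `f_k` is the
Hardy–Weinberg genotype probability under source *k*. Standard errors
decompose into a mixture-sampling component (inverse observed information)
and a baseline-sampling component (parametric resampling of baseline
counts); percentile bootstrap CIs resample mixture individuals and
baseline gene copies.

**Empirical Bayes pairwise F_ST.** For weakly differentiated
(high-gene-flow) populations: allele frequencies of a pair are modelled as
Dirichlet(θ·p̄) around the survey-pooled frequencies, θ is estimated by
maximizing the Dirichlet-multinomial marginal likelihood over loci, and
`F_ST = 1/(1+θ)` with a finite-pool correction. UPGMA dendrograms are
built from the pairwise matrix and written as Newick.

**Diversity statistics.** Rarefied allelic and haplotype richness
`Σ_a [1 − C(N−N_a, g)/C(N, g)]`, unbiased expected heterozygosity,
haplotype diversity, per-site nucleotide diversity (complete deletion),
and a permutation G-test of population differentiation (Fisher-combined
across loci).

**Stocking dynamics.** Mark-survey expansion of the hatchery fraction
`P_h = (n_marked/n_checked)/q`; effort-corrected cumulative recapture
rates per release cohort; exponential-decline fits `y = a·exp(−λx)` with
rate comparison (`z = |λ_A−λ_B|/√(SE_A²+SE_B²)`, one-sided p); the
per-generation fitness conversion `1 − exp(−λG)`; and a deterministic
wild-gene replacement recursion for a semelparous population: genotypes
WW/WH/HH with fitnesses 1, (1+f)/2, f, Hardy–Weinberg reproduction, and
stocked HH recruits added at rate R per wild-born recruit — yielding
generations-to-replacement and equilibrium surfaces over (f, R).

**Trend attribution.** Pearson correlations and stepwise-AIC multiple
regression of wild catch on habitat (seaweed harvest), fishing effort and
other covariates, via `lm`/`step` with the full-Gaussian AIC convention.

**Synthetic data.** A first-class generator (Dirichlet island model for
baselines, HWE genotypes, mixtures with known origins, release cohorts
with lognormal rate noise, covariate series with known coefficients) so
every stage is testable end to end without any deposited data.

## Worked example

Using the small synthetic dataset shipped with the package (three samples
of 24 fish at five microsatellite loci; `HATCH` is a synthetic hatchery
stand-in):

```r
library(HatcheryImpact)

gen <- system.file("extdata", "synthetic_baselines.gen", package = "HatcheryImpact")
gt  <- readGenepop(gen, pop_names = c("HATCH", "INNER", "OUTER"))
gt
#> GenotypeTable: 72 individuals, 5 loci, 3 populations

diversityReport(gt)
#>   population allelic_richness expected_heterozygosity rarefaction_g
#> 1      HATCH              5.2                   0.715            48
#> 2      INNER              5.6                   0.744            48
#> 3      OUTER              5.6                   0.724            48

ebFst(alleleCounts(gt))
#> EBFstMatrix: 3 populations; mean pairwise F_ST 0.02841 +/- 0.01002 (s.d.)
```

The rarefied richness standardizes every sample to 48 gene copies, so the
slightly lower `HATCH` value reflects genuinely fewer alleles, not a
smaller sample. The mean pairwise F_ST of ~0.03 matches the generator's
target differentiation for this fixture.

Estimate the hatchery contribution to a mixed sample (here a simulated
mixture whose true composition is 40% `HATCH`):

```r
two <- gt[populations(gt) %in% c("HATCH", "OUTER")]
mix <- simulateMixture(two, c(0.4, 0.6), n = 60, seed = 7)
est <- emEstimate(mix$mixture, alleleCounts(two), seed = 7)
est <- baselineAwareSE(est, mix$mixture, alleleCounts(two), seed = 7)
est
#> MixtureEstimate (conditional-ML GSI)
#>       proportion     se
#> HATCH     0.4913 0.0833
#> OUTER     0.5087 0.0833
```

The truth (0.40) lies ~1.1 SE below the estimate — within sampling error
for 60 fish at five loci.

Fit the decline of cohort recapture rates and convert it to a
per-generation survival loss (generation time 4.8 years):

```r
rc    <- simulateReleaseCohorts(simConfig(seed = 7, years = 25))
rates <- cumulativeRecaptureRate(rc, max_age = 8)
fit   <- fitExponentialDecay(rates$release_year - 1, rates$rate)
fit
#> DecayFit: y = 0.0569 exp(-0.1258 x)  [nls]
#>   rate SE 0.0077, t = 16.351, P = 3.7e-14 (df = 23)

fitnessReductionPerGeneration(decayRate(fit), 4.8, decayRate(fit, se = TRUE))
#>  reduction         se   se_delta
#> 0.45326928 0.03692642 0.02018881
```

A 12.6%-per-year decline compounds to a ~45% survival loss per
generation. Finally, the replacement recursion: with equal hatchery
fitness (f = 1) and a stocking rate of 0.1 per wild-born recruit,

```r
c(half = generationsToThreshold(1, 0.1, 0.5),
  one_percent = generationsToThreshold(1, 0.1, 0.01))
#>        half one_percent
#>           8          49
```

half the wild genes are replaced within 8 generations and 99% within 49.
`runDemo(seed)` chains all stages into one reproducible report.

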