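---
title: "Models and methods behind HatcheryImpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind HatcheryImpact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HatcheryImpact)
```

This vignette explains the statistical models the package implements, the
assumptions they rest on, the numerical choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the test suite and the
acceptance script themselves compute.

## The monitoring problem

A hatchery program releases captively bred juveniles into a fished wild
population. Monitoring produces four kinds of data: (i) mark surveys of
landings (a morphological hatchery mark checked on landed fish), (ii)
release-cohort recapture records by age, (iii) microsatellite genotypes
and mtDNA control-region haplotypes for hatchery, farmed and wild samples,
and (iv) catch/effort/habitat covariate series. The package turns these
into four families of estimates: hatchery contribution to landings and to
the gene pool, fitness decay of hatchery cohorts, long-run wild-gene
replacement under continued stocking, and regression attribution of
wild-catch trends.

## Conditional-ML genetic stock identification

The mixture sample's likelihood is
$L(\pi) = \prod_i \sum_k \pi_k f_k(x_i)$, where $f_k(x_i)$ is the product
over loci of Hardy–Weinberg genotype probabilities under source $k$'s
allele frequencies. The *conditional* formulation holds the baseline
frequencies fixed at their sample estimates; baseline sampling error is
then handled in the standard errors rather than in the point estimator.
This matches the classical two-stage GSI workflow in which point
estimation and error propagation are separated.

Assumptions: loci independent (linkage equilibrium), HWE within sources,
mixture individuals sampled independently. EM is run from a uniform start
plus nine Dirichlet(1) random starts (default `n_starts = 10`), stopping
when $\max_k |\Delta\pi_k| < 10^{-7}$ (default `tol`), capped at 10,000
iterations; the log-likelihood is asserted non-decreasing at every
iteration, so a monotonicity violation fails loudly instead of returning
a wrong optimum.

**Smoothing.** Baseline frequencies use
$\hat p_a = (x_a + 1/A)/(2n_k + 1)$, where $A$ is the number of alleles
at the locus over the union of baseline and mixture alleles. Each allele
receives pseudo-count $1/A$ (one virtual gene copy split across alleles),
so a mixture fish carrying an allele unseen in some baseline retains a
small positive likelihood there instead of being assigned to the other
sources with certainty. Classical GSI tools do this internally without
documenting it; the choice only matters for rare alleles and vanishes as
baselines grow.

**Standard errors.** The mixture-sampling component is the inverse
observed information of the conditional likelihood at $\hat\pi$
(outer-product form on the $K-1$ free parameters; the $K$-th source's
variance follows from the sum constraint). The baseline component
resamples each baseline's allele counts parametrically (multinomial with
the observed sample sizes), re-runs EM warm-started at $\hat\pi$, and
takes the empirical standard deviation over 200 resamples (default).
Total SE combines the two in quadrature. In the diagnostic-allele limit
(two baselines fixed for disjoint alleles) the information SE reduces to
the binomial $\sqrt{\pi(1-\pi)/n}$, which the tests assert. Bootstrap
percentile intervals (default 1,000 replicates) resample mixture
individuals and baseline gene copies.

## Empirical Bayes pairwise F_ST

For high-gene-flow marine populations, pairwise F_ST values of order
0.001–0.01 drown in sampling noise under moment estimators applied to a
single pair. The package uses a Dirichlet-multinomial hierarchy: true
frequency vectors of the two populations at locus $l$ are
$\mathrm{Dir}(\theta \bar p_l)$ around baseline frequencies $\bar p_l$,
observed counts are multinomial draws, and a single concentration
$\theta$ shared across loci is estimated by maximizing the product of
Dirichlet-multinomial marginal likelihoods. Under this model Wright's
$F_{ST} = 1/(1+\theta)$. The 1-D optimization runs on the log scale over
$[10^{-4}, 10^6]$ with tolerance $10^{-8}$; an optimum at the bracket
boundary is flagged, never silent. The point estimate is the mode of the
marginal likelihood; a posterior-mean variant would be a natural
extension but is not implemented.

**The choice of $\bar p$ matters.** With only the pair available,
$\bar p$ must be the pair's own pooled frequencies — but deviations of
two samples about their own mean retain only half the between-population
degrees of freedom, so for very weak differentiation the marginal
likelihood can push $\theta$ to the boundary and the estimate to zero.
`ebFstPair()` therefore accepts an external $\bar p$, and `ebFst()`
(the survey-level entry point) supplies the pooled frequencies of *all*
$P$ populations. Even then a first-order bias remains: the mean squared
deviation of a sample frequency from the $P$-population pooled mean is
$(P-1)/P$ of its variance (Bessel's factor), and $1/P$ of the multinomial
noise is absorbed into the pool. Writing $d = 1/(1+\hat\theta)$ for the
fitted dispersion and $\tilde N$ for the harmonic-mean gene copies per
population, inverting that relation gives the finite-pool correction

$$\hat F_{ST} = \Bigl(d + \tfrac{1}{\tilde N P}\Bigr)\frac{P}{P-1},$$

which `ebFst()` applies to every pair (for $P = 2$ the correction is
noise-dominated and is not applied; the pair-only estimate is documented
as conservative for weak differentiation). The calibration test in the
suite — twenty island-model populations at true $F_{ST} = 0.01$, five
loci of thirty alleles, fifty diploids per population, ten replicates —
checks the corrected estimator against generator truth within
Monte-Carlo error, alongside an independently coded Weir–Cockerham
estimator validating the generator itself.

UPGMA trees are built on the pairwise matrix by average-linkage
agglomeration (`hclust`), with labels sorted lexicographically first so
tie-breaks are deterministic; node heights are half the merge distance,
giving an ultrametric `phylo` tree serialized as Newick (labels with
whitespace are single-quoted).

## Diversity and differentiation statistics

Rarefied richness uses the hypergeometric form
$\sum_a [1 - \binom{N-N_a}{g}\big/\binom{N}{g}]$ (computed via `lchoose`
for stability), the expected number of distinct alleles among $g$ gene
copies drawn without replacement; the suite checks it against exhaustive
enumeration of all $\binom{N}{g}$ subsamples wherever that is feasible.
The default $g$ is the smallest per-locus sample size, matching standard
rarefaction practice. Expected heterozygosity uses the unbiased
$\frac{2n}{2n-1}(1-\sum p_i^2)$; haplotype diversity the haploid
analogue; nucleotide diversity averages pairwise differences per included
site.

Haplotype collapsing uses **complete deletion**: any site with a gap or
N in *any* sequence is excluded alignment-wide before grouping. This is
the conservative common default; whether ambiguous bases should instead
be treated as distinct states is a genuine open choice, and complete
deletion is the documented one here. Alignment positions are reported
1-based.

The differentiation test replaces a Markov-chain exact test with a
permutation test: the statistic is the multinomial log-likelihood-ratio
$G$ over the 2×A allele-count table, individuals (or haploid copies) are
permuted between the two populations, ties count as at least as extreme,
and $p = (1 + \#\{G_{perm} \ge G_{obs}\})/(n_{perm}+1)$ — so $p$ can
never fall below the permutation floor. Per-locus p-values combine by
Fisher's method; across many population pairs, Bonferroni correction is
the intended adjustment. The permutation formulation is asymptotically
equivalent to the exact test under the null and is far easier to verify;
the suite calibrates its type-I error at $\alpha = 0.05$ over 500 null
replicates.

## Stocking dynamics

**Mark-survey expansion.** $P_h = (n_{marked}/n_{checked})/q$ with mark
incidence $q \in (0,1]$ defaulting to 1 (the deformity mark is treated as
fully penetrant in hatchery fish; $q$ is a parameter because real marks
are imperfect). The SE scales the raw binomial SE by $1/q$. Strata pool
by landings-weighted average.

**Recapture decline.** The effort-corrected cumulative recapture rate of
a cohort divides each age's recaptures by that recapture year's relative
fishing effort before summing and dividing by the number released.
Decline fits use $y = a e^{-\lambda x}$ by original-scale nonlinear least
squares (`nlsLM`), initialized from the log-linear OLS fit, with
asymptotic SEs and a $t$-test of $\lambda \ne 0$ on $n-2$ df. The
log-scale OLS variant is exposed as `method = "loglinear"`: under
multiplicative (lognormal) rate noise — the noise model the generator
uses, chosen because rates are positive and their dispersion scales with
their level — the log-scale fit is the exactly matched model, so its
intervals are the calibrated ones and the coverage test exercises that
variant. Two fitted rates are compared by
$z = |\lambda_A - \lambda_B| / \sqrt{SE_A^2 + SE_B^2}$ with a
**one-sided** normal p-value — the convention identified from the
published $(z, P)$ pair — plus simple-average and inverse-variance-pooled
combined rates (the simple average is what matches the published summary
rate to rounding; both are reported).

**Fitness conversion.** The per-generation survival reduction is
$1 - e^{-\lambda G}$ for generation time $G$ (years). Two error
conventions are reported: `se` $= G\,SE_\lambda$, the first-order SE of
the per-generation decay exponent $\lambda G$ — the convention used in
field reports of per-generation loss — and `se_delta`
$= G e^{-\lambda G} SE_\lambda$, the full delta-method SE of the
transformed proportion. They differ by the factor $e^{-\lambda G}$
(≈0.5 at the study's scale); reporting both makes the choice explicit.

**Replacement recursion.** A semelparous population with genotypes WW
(wild), WH, HH (hatchery) at one locus, equal sex ratio, fitnesses
$1,\ (1+f)/2,\ f$. One generation: fitness-weight the adult genotype
proportions; form the W-gamete frequency $p^*$; wild-born offspring at
Hardy–Weinberg in $p^*$; add stocked HH recruits at $R$ per wild-born
recruit, i.e. next adults $= [\mathrm{HWE}(p^*) + R\cdot HH]/(1+R)$. The
interpretation of $R$ as stocked-per-wild-born (not a fraction of the
total) is forced by the benchmark generation counts the recursion must
reproduce: at $f = 1$ the recursion collapses to
$p_{t+1} = p_t/(1+R)$ exactly, giving
$\lceil \ln 0.01 / \ln(1/1.1) \rceil = 49$ generations to 99%
replacement at $R = 0.1$ (and 8 to 50%). Generation 0 is the pre-stocking
state; the threshold test is strict (<). The wild gene persists at an
interior equilibrium exactly when $(1+f)/(2f(1+R)) > 1$ — the low-$p$
linearization of the map — and the suite cross-validates this boundary
against iteration over an $(f, R)$ grid. Equilibria iterate to
$\max|\Delta| < 10^{-12}$ with a $10^6$-generation cap; non-convergence
is flagged per cell. The model is deterministic and unstructured: no
age structure, no finite-population drift, no overlapping generations.

## Trend regression

Pearson correlations use $t = r\sqrt{df/(1-r^2)}$, $df = n-2$,
two-sided. OLS and stepwise selection go through `lm` and `step` — the
same machinery the original analysis used — wrapped behind the package's
result type. AIC is reported in the full-Gaussian convention
(`stats::AIC`), so levels are comparable across nested fits on one
response; selection depends only on differences, which are identical
under any additive constant. The default direction is backward from the
full model ("both" is available); no time-lag terms are included,
mirroring the design choice of the original analysis (overlapping
generations make lag attribution ill-posed). Rank-deficient designs are
rejected naming the collinear columns.

## The synthetic-data generator

The generator defines the conditions under which the package's claims are
tested:

* **Baselines**: per-locus frequencies for each population drawn
  Dirichlet with mean $\bar p$ (flat-Dirichlet draw by default) and
  concentration $(1-F_{ST})/F_{ST}$, so expected Wright's $F_{ST}$
  equals the target; $F_{ST}=0$ degenerates to identical frequencies.
  This island-model parameterization is a stand-in — the field data's
  true generative process is unknown — and carries no mutation model,
  linkage, or coalescent structure.
* **Genotypes**: HWE draws, independent loci; 3-digit allele codes in
  the Genepop dialect.
* **Mixtures**: origins drawn from the true proportions, genotypes from
  the named source's frequency estimates; true origins returned.
* **Release cohorts**: cohort $y$ has true cumulative recapture rate
  $r_0 e^{-\lambda y}$ times lognormal noise $e^{N(0,\sigma^2)}$;
  per-age recaptures decline geometrically (ratio 0.55 over ages 1–8,
  the last a plus group) and are modulated by a linearly declining
  effort index so the effort-corrected cumulative rate recovers the
  cohort rate exactly. Defaults $\lambda = 0.139$ per year and
  $r_0 = 0.06$ sit at the study's scale; $\sigma = 0.2$ is the package's
  realism choice for rate noise (the field data's noise model is not
  reported).
* **Covariates**: a rising habitat (seaweed-harvest) series and a
  declining effort series, each with strong interannual variability
  (sd 300 t and 250 units around their trends — without it the two
  trends would be nearly collinear and no selection procedure could
  separate them, which real harvest series do not exhibit), an inert SST
  column and an inert hatchery-fraction column; the response is the
  linear combination with coefficients defaulting to the published
  selected-model estimates (intercept 254.48, habitat 0.0982, effort
  −0.1226) plus Gaussian noise (sd 55 t, chosen so $R^2 \approx 0.7$,
  the level of the original fit); true coefficients are recorded.

A single global seed fans out to per-generator streams through a
hash-based scheme, so adding a generator never shifts another's draws,
and every generator is bit-reproducible under a fixed seed.

What passing tests on these data do **not** show: robustness to null
alleles and scoring error, to HWE/linkage violations within baselines, to
age-structured recapture dynamics, or to non-lognormal rate noise. The
generator's realism ends at the assumptions the estimators themselves
make.

## Problem sizes and numerical conventions

The suite's calibration experiments use: 20 populations × 50 diploids ×
5 loci × 30 alleles for the F_ST recovery (10 replicates, with a
50-replicate Weir–Cockerham check of the generator); 500 null replicates
× 199 permutations for type-I calibration; 100 replicates of 25 cohorts
for decline-fit coverage; 100 replicates of 167-fish mixtures on
100-fish baselines at $F_{ST} = 0.05$ for GSI recovery — sizes chosen to
mirror the study's scale (642 genotyped fish, 27-year series, 167-fish
mixture sample) while keeping the suite comfortably re-runnable.

Conventions worth knowing: missing genotypes are excluded per locus
(counts conserve twice the typed individuals); Genepop "0"-coded alleles
mark the whole genotype missing; 2- vs 3-digit encodings are
auto-detected and may not be mixed; permutation ties count as extreme
(conservative); EM ties across restarts resolve to the best
log-likelihood; UPGMA ties resolve lexicographically; all randomized
routines take explicit seeds; proportions are validated to sum to 1
within $10^{-9}$ (generator) / $10^{-8}$ (estimates).

## Known limitations

* The replacement model is single-locus, deterministic and semelparous;
  it bounds, but does not simulate, iteroparous overlapping-generation
  dynamics.
* EB F_ST reports a likelihood-mode plug-in, not a posterior mean; for
  an isolated pair (no survey context) weak differentiation is estimated
  conservatively.
* The GSI estimator is conditional-ML; a joint (unconditional)
  likelihood over baselines and mixture, and Bayesian mixture variants,
  are out of scope.
* The permutation differentiation test approximates, and does not
  replicate, Markov-chain exact p-values on a given dataset.
* Reproducing the original program's published field values requires its
  deposited genotype and supplementary catch data, which are not bundled;
  the synthetic generator exercises every code path at the same scale
  instead.
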