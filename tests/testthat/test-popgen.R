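test_that("allele counts exclude missing genotypes and conserve ploidy", {
  arr <- array(NA_integer_, dim = c(3, 2, 2))
  arr[1, 1, ] <- c(101L, 101L)
  arr[2, 1, ] <- c(101L, 102L)
  arr[3, 1, ] <- c(102L, 102L)
  # locus 2 all-missing
  gt <- genotypeTable(c("a", "b", "c"), "p1", arr, c("l1", "l2"))
  aft <- alleleCounts(gt)
  expect_equal(unname(aft@counts[["l1"]]["p1", ]), c(3L, 3L))
  expect_equal(sum(aft@counts[["l2"]]), 0L)
  expect_equal(sum(aft@counts[["l1"]]), 6L)  # 2 x 3 typed individuals
})

test_that("rarefied richness matches the exhaustive subsampling oracle", {
  # N = 4 copies (a, a, b, c), g = 2: enumerate all C(4,2) subsamples
  counts <- c(a = 2, b = 1, c = 1)
  expect_equal(HatcheryImpact:::rarefiedRichness(counts, 2),
               rarefactionBruteForce(counts, 2), tolerance = 1e-12)
  # sweep: every configuration with C(N, g) <= 1e5
  set.seed(8)
  for (rep in 1:25) {
    counts <- stats::rpois(sample(2:5, 1), 4) + 1
    N <- sum(counts)
    for (g in unique(c(1, 2, min(3, N), N))) {
      if (choose(N, g) > 1e5) next
      expect_equal(HatcheryImpact:::rarefiedRichness(counts, g),
                   rarefactionBruteForce(counts, g), tolerance = 1e-10)
    }
  }
  # degenerate cases
  expect_equal(HatcheryImpact:::rarefiedRichness(c(7), 3), 1)     # monomorphic
  expect_equal(HatcheryImpact:::rarefiedRichness(c(4, 2, 1), 1), 1)  # g = 1
  expect_equal(HatcheryImpact:::rarefiedRichness(c(4, 2, 1), 7), 3)  # g = N
  expect_error(HatcheryImpact:::rarefiedRichness(c(2, 2), 0), ">= 1")
})

test_that("haplotype richness applies the same rarefaction to haploid counts", {
  expect_equal(haplotypeRichness(c(5), 3), 1)
  expect_equal(haplotypeRichness(c(2, 2, 1), 5), 3)  # g = N -> observed count
  expect_equal(haplotypeRichness(c(3, 1, 1), 3),
               rarefactionBruteForce(c(3, 1, 1), 3), tolerance = 1e-12)
  m <- rbind(p1 = c(3, 1, 1), p2 = c(5, 0, 0))
  expect_equal(unname(haplotypeRichness(m, 3)),
               c(rarefactionBruteForce(c(3, 1, 1), 3), 1), tolerance = 1e-12)
})

test_that("unbiased expected heterozygosity follows the 2n/(2n-1) correction", {
  mkAft <- function(counts) {
    new("AlleleFrequencyTable", pops = "p1", loci = "l1",
        counts = list(l1 = matrix(counts, 1, length(counts),
                                  dimnames = list("p1", seq_along(counts)))))
  }
  expect_equal(unname(expectedHeterozygosity(mkAft(c(10, 0)))$per_locus[1, 1]), 0)
  # p = (0.5, 0.5), n = 5 -> (10/9) * 0.5
  expect_equal(unname(expectedHeterozygosity(mkAft(c(5, 5)))$per_locus[1, 1]),
               10 / 9 * 0.5, tolerance = 1e-12)
  # n < 2 undefined
  expect_true(is.na(expectedHeterozygosity(mkAft(c(1, 1)))$per_locus[1, 1]))
})

test_that("haplotype diversity: degenerate and hand-computed cases", {
  expect_equal(haplotypeDiversity(c(9)), 0)
  expect_equal(haplotypeDiversity(c(1, 1)), 1)
  expect_equal(haplotypeDiversity(c(3, 1)), 0.5, tolerance = 1e-12)
})

test_that("nucleotide diversity uses complete deletion and pairwise differences", {
  expect_equal(nucleotideDiversity(haplotypeAlignment(rep("ACGT", 4), "p")), 0)
  # two 465-bp sequences differing at one site
  s1 <- paste(rep("A", 465), collapse = "")
  s2 <- paste(c(rep("A", 464), "C"), collapse = "")
  expect_equal(nucleotideDiversity(haplotypeAlignment(c(s1, s2), "p")),
               1 / 465, tolerance = 1e-12)
  # invariant under sequence reordering
  set.seed(5)
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C"), 30, replace = TRUE), collapse = ""), "")
  a1 <- haplotypeAlignment(seqs, "p")
  a2 <- haplotypeAlignment(rev(seqs), "p")
  expect_equal(nucleotideDiversity(a1), nucleotideDiversity(a2))
  # gapped site is excluded before counting differences
  aln <- haplotypeAlignment(c("AC-T", "ACAT"), "p")
  expect_equal(nucleotideDiversity(aln), 0)
})

test_that("permutation differentiation test bounds and extreme cases", {
  # disjoint fixed alleles -> minimal attainable p
  tab <- rbind(a = c(40, 0), b = c(0, 40))
  r <- permDiffTest(tab, n_perm = 199, seed = 1)
  expect_equal(unname(r$per_locus), 1 / 200)
  # identical content -> p never below the permutation floor, typically large
  tab2 <- rbind(a = c(20, 20), b = c(20, 20))
  r2 <- permDiffTest(tab2, n_perm = 199, seed = 1)
  expect_gte(r2$per_locus[[1]], 1 / 200)
  expect_gt(r2$per_locus[[1]], 0.5)
  expect_error(permDiffTest(rbind(c(0, 0), c(1, 2)), n_perm = 199), "zero copies")
  expect_error(permDiffTest(tab, n_perm = 50), ">= 99")
})

test_that("genotype-based permutation test detects a planted difference", {
  cfg <- simConfig(seed = 17, n_populations = 2, target_fst = 0.15,
                   sample_sizes = 40)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 40, seed = 17)
  pops <- sort(unique(gt@pop))
  r <- permDiffTest(gt, pops[1], pops[2], n_perm = 199, seed = 3)
  expect_lt(r$p, 0.05)
  expect_length(r$per_locus, 5)
})

test_that("diversity report assembles microsatellite and mtDNA statistics", {
  cfg <- simConfig(seed = 19, n_populations = 3, sample_sizes = 30)
  gt <- simulateGenotypes(simulateBaselineFrequencies(cfg), 30, seed = 19)
  set.seed(19)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  aln <- haplotypeAlignment(seqs, rep(c("pop01", "pop02", "pop03"), each = 10))
  rep_ <- diversityReport(gt, aln)
  expect_equal(nrow(rep_), 3)
  expect_true(all(rep_$expected_heterozygosity >= 0 &
                    rep_$expected_heterozygosity <= 1))
  expect_true(all(rep_$haplotype_diversity <= 1, na.rm = TRUE))
  expect_true(all(rep_$allelic_richness >= 1))
  expect_true(all(rep_$allelic_richness <=
                    vapply(alleleCounts(gt)@counts, ncol, 0L) |> max()))
})
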