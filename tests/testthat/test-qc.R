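test_that("allele frequencies and MAF count B alleles over non-missing calls", {
  g <- toy_geno(matrix(c(0L, 0L, 1L, 2L), 4, 1))
  af <- allele_frequency(g)
  expect_equal(af$freqB, 0.375)
  expect_equal(af$maf, 0.375)
  af2 <- allele_frequency(toy_geno(matrix(c(2L, 2L, 2L), 3, 1)))
  expect_equal(af2$freqB, 1)
  expect_equal(af2$maf, 0)
  af3 <- allele_frequency(toy_geno(matrix(rep(1L, 4), 4, 1)))
  expect_equal(af3$freqB, 0.5)
  expect_equal(af3$maf, 0.5)
})

test_that("exact HWE test matches the printed landmark cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(1, 0, 0), 1.0)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)  # monomorphic
})

test_that("exact HWE test agrees with brute-force enumeration on random tables", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(1:60, 1)
    nAB <- sample(0:n, 1)
    nAA <- if (n > nAB) sample(0:(n - nAB), 1) else 0
    nBB <- n - nAB - nAA
    expect_equal(hwe_exact_test(nAA, nAB, nBB), hwe_brute(nAA, nAB, nBB),
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni threshold is alpha over n", {
  expect_equal(bonferroni_threshold(0.05, 50000), 1e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(1.0, 4), 0.25)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("QC cascade counts planted violations sequentially in table order", {
  g <- simulate_hwe_genotypes(n_samples = 50, n_chromosomes = 1,
                              markers_per_chrom = 500,
                              freq_range = c(0.2, 0.8), seed = 21)
  pl <- plant_qc_violations(g, n_low_maf = 5, n_low_call = 3, n_hwe = 1,
                            n_unplaced = 2, n_x = 4, n_bad_samples = 2,
                            seed = 22)
  qc <- run_qc(pl$genotypes, qc_config())
  expect_equal(qc$report$removed[1:6], c(2, 5, 3, 1, 2, 4))
  expect_equal(qc$report$remaining[7], 48)
  expect_equal(qc$report$remaining[8], 500 - 15)
  # planted marker ids are exactly the removed ones
  kept <- qc$genotypes$map$id
  expect_false(any(unlist(pl$truth[1:5]) %in% kept))
})

test_that("QC is idempotent: second pass removes nothing", {
  g <- simulate_hwe_genotypes(n_samples = 40, n_chromosomes = 2,
                              markers_per_chrom = 200,
                              freq_range = c(0.2, 0.8), seed = 31)
  pl <- plant_qc_violations(g, n_low_maf = 3, n_hwe = 1, seed = 32)
  qc1 <- run_qc(pl$genotypes)
  qc2 <- run_qc(qc1$genotypes,
                qc_config(n_tests_for_bonferroni = n_markers(pl$genotypes)))
  expect_equal(qc2$report$removed[1:6], rep(0, 6))
  expect_equal(qc2$genotypes$calls, qc1$genotypes$calls)
})

test_that("planting nothing removes nothing", {
  g <- simulate_hwe_genotypes(n_samples = 30, n_chromosomes = 1,
                              markers_per_chrom = 120,
                              freq_range = c(0.2, 0.8), seed = 41)
  qc <- run_qc(g)
  expect_equal(qc$report$removed[1:6], rep(0, 6))
})

test_that("heterozygosity summaries follow their definitions", {
  # maximum He at p = 0.5
  g <- toy_geno(matrix(c(0L, 2L, 1L, 1L), 4, 1))
  d <- heterozygosity(g)
  expect_equal(d$per_snp$He, 0.5)
  g2 <- toy_geno(matrix(c(1L, 1L, 0L, 2L), 4, 1))
  expect_equal(heterozygosity(g2)$per_snp$Ho, 0.5)
  # binomial oracle: at HWE with p = 0.3, E[Ho] = 0.42
  gh <- hwe_geno(500, 60, p = 0.3, seed = 42)
  mho <- heterozygosity(gh)$means[["mean_Ho"]]
  se <- sqrt(0.42 * 0.58 / (500 * 60))    # upper bound ignoring marker corr
  expect_lt(abs(mho - 0.42), 3 * max(se, 0.42 * 0.05))
})

test_that("Ho tracks He under random mating and drops below it with autozygosity", {
  g <- simulate_hwe_genotypes(n_samples = 60, n_chromosomes = 2,
                              markers_per_chrom = 400, seed = 51)
  d <- heterozygosity(g)
  expect_lt(abs(d$means[["mean_Ho"]] - d$means[["mean_He"]]), 0.01)
  inj <- inject_autozygosity(g, 0.3, tract_length_mb = 3, seed = 52)
  d2 <- heterozygosity(inj$genotypes)
  expect_lt(d2$means[["mean_Ho"]], d2$means[["mean_He"]] - 0.05)
})

test_that("PCA separates drifted populations and respects degeneracies", {
  set.seed(61)
  nm <- 300
  p0 <- runif(nm, 0.2, 0.8)
  fst <- 0.1
  drift <- function(p) rbeta(nm, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  p1 <- drift(p0); p2 <- drift(p0)
  draw <- function(p, n) t(replicate(n, rbinom(nm, 2, p)))
  calls <- rbind(draw(p1, 25), draw(p2, 25))
  g <- genotype_matrix(calls, toy_map(nm),
                       population = rep(c("A", "B"), each = 25))
  pc <- pca_genotypes(g, 4)
  a <- pc$scores[1:25, 1]; b <- pc$scores[26:50, 1]
  expect_true(max(a) < min(b) || max(b) < min(a))   # zero overlap on PC1
  expect_true(all(diff(pc$var_fraction) <= 1e-12))  # sorted descending
  expect_lte(sum(pc$var_fraction), 1 + 1e-9)

  # duplicated sample gets identical coordinates
  g2 <- genotype_matrix(calls[c(1, 1, 2:10), ], toy_map(nm))
  pc2 <- pca_genotypes(g2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-9)

  # all-identical samples are degenerate
  g3 <- genotype_matrix(matrix(1L, 5, 10), toy_map(10))
  expect_error(pca_genotypes(g3), "identical|polymorphic")
})

test_that("PCA variance fractions are invariant to sample order", {
  g <- hwe_geno(30, 100, p = 0.4, seed = 71)
  perm <- sample(30)
  vf1 <- pca_genotypes(g, 3)$var_fraction
  vf2 <- pca_genotypes(subset_genotypes(g, samples = perm), 3)$var_fraction
  expect_equal(vf1, vf2, tolerance = 1e-9)
})
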