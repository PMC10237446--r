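test_that("minimum ROH SNP count follows the false-positive calibration", {
  expect_equal(min_roh_snps(42640, 88, 0.05, 0.38), 38L)
  expect_equal(min_roh_snps(1000, 1, 0.05, 0.5), 15L)
  # as mean_het -> 1 the required run length collapses to the floor
  expect_equal(min_roh_snps(50000, 100, 0.05, 1 - 1e-12), 1L)
  expect_error(min_roh_snps(1000, 10, 0.05, 1), "mean_het")
  expect_error(min_roh_snps(1000, 10, 0.05, 0), "mean_het")
})

# fixture: one chromosome, homozygous core with heterozygote-rich flanks
roh_fixture <- function(core_het_at = integer(0), n_core = 60,
                        n_flank = 40, spacing = 5e4, seed = 1) {
  set.seed(seed)
  flank <- function(n) sample(c(0L, 1L, 2L), n, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25))
  core <- rep(0L, n_core)
  core[core_het_at] <- 1L
  calls <- matrix(c(flank(n_flank), core, flank(n_flank)), nrow = 1)
  toy_geno(calls, spacing = spacing)
}

test_that("a planted homozygous run is detected as exactly one segment", {
  g <- roh_fixture()
  p <- roh_params(min_snp_count = 40)
  segs <- detect_roh(g, p)
  expect_equal(nrow(segs), 1)
  core_start <- g$map$pos_bp[41]; core_end <- g$map$pos_bp[100]
  # detected run covers the planted core (may extend into homozygous flank)
  expect_lte(segs$start_bp, core_start)
  expect_gte(segs$end_bp, core_end)
  expect_lte(segs$n_het, 1)
})

test_that("a fully heterozygous sample yields no segments", {
  g <- toy_geno(matrix(1L, 1, 100), spacing = 5e4)
  expect_equal(nrow(detect_roh(g, roh_params(min_snp_count = 20))), 0)
})

test_that("one internal heterozygote is tolerated, three break the run", {
  g1 <- roh_fixture(core_het_at = 30)
  p <- roh_params(min_snp_count = 40)
  segs1 <- detect_roh(g1, p)
  expect_equal(nrow(segs1), 1)
  expect_gte(segs1$n_snps, 40)
  g3 <- roh_fixture(core_het_at = c(15, 30, 45))
  segs3 <- detect_roh(g3, p)
  expect_equal(nrow(segs3), 0)   # best 1-het sub-run is ~30 SNPs < 40
})

test_that("runs are split at large gaps", {
  calls <- matrix(0L, 1, 60)
  pos <- c(seq(5e4, by = 5e4, length.out = 30),
           seq(5e4 * 30 + 2e6, by = 5e4, length.out = 30))  # 2 Mb gap
  g <- genotype_matrix(calls, marker_map(paste0("m", 1:60), 1, pos))
  segs <- detect_roh(g, roh_params(min_snp_count = 20, max_gap_kb = 1000))
  expect_equal(nrow(segs), 2)
})

test_that("ROH detection is invariant to sample order", {
  g <- simulate_hwe_genotypes(n_samples = 12, n_chromosomes = 2,
                              markers_per_chrom = 300, seed = 401)
  inj <- inject_autozygosity(g, 0.15, tract_length_mb = 4, seed = 402)
  p <- roh_params(min_snp_count = 25)
  a <- detect_roh(inj$genotypes, p)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  b <- detect_roh(subset_genotypes(inj$genotypes, samples = perm), p)
  a <- a[order(a$sample_id, a$chrom, a$start_bp), ]
  b <- b[order(b$sample_id, b$chrom, b$start_bp), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("F_ROH is coverage over autosome length with a 1 Mb floor", {
  segs <- data.frame(sample_id = c("s1", "s1", "s2"), population = "p",
                     chrom = c(1L, 2L, 1L), start_bp = c(1, 1, 1),
                     end_bp = c(1, 1, 1), n_snps = 50L, n_het = 0L,
                     length_kb = c(12420, 12420, 800))
  fr <- f_roh(segs, c("s1", "s2", "s3"), l_auto_bp = 2484e6)
  expect_equal(fr$F_ROH, c(0.01, 0, 0))       # 24.84 Mb / 2484 Mb; 0.8 Mb floored
  # whole-autosome coverage gives 1
  whole <- data.frame(sample_id = "s1", population = "p", chrom = 1L,
                      start_bp = 1, end_bp = 1, n_snps = 10L, n_het = 0L,
                      length_kb = 1e6)
  expect_equal(f_roh(whole, "s1", 1e9)$F_ROH, 1)
  # no segments
  expect_equal(f_roh(segs[0, ], "s1", 1e9)$F_ROH, 0)
})

test_that("GRM-family estimators reproduce hand-evaluated cases", {
  # two individuals heterozygous at one locus: p = 0.5
  g <- toy_geno(matrix(c(1L, 1L), 2, 1))
  f <- grm_inbreeding(g)
  expect_equal(f$Fhat1, c(-1, -1))
  expect_equal(f$Fhat3, c(-1, -1))
  # an all-homozygous individual has Fhat2 = 1 exactly
  g2 <- toy_geno(rbind(c(0L, 2L, 0L, 2L),
                       c(1L, 1L, 0L, 2L),
                       c(0L, 1L, 1L, 2L)))
  f2 <- grm_inbreeding(g2)
  expect_equal(f2$Fhat2[1], 1)
})

test_that("GRM-family estimators centre at zero under random mating", {
  g <- simulate_hwe_genotypes(n_samples = 200, n_chromosomes = 4,
                              markers_per_chrom = 500, seed = 411)
  f <- grm_inbreeding(g)
  expect_lt(abs(mean(f$Fhat1)), 0.02)
  expect_lt(abs(mean(f$Fhat2)), 0.02)
  expect_lt(abs(mean(f$Fhat3)), 0.02)
  expect_true(all(f$Fhat2 <= 1 + 1e-12))
})

test_that("ROH length classes bin segments with a 1 Mb floor", {
  segs <- data.frame(sample_id = c("s1", "s1", "s2"), population = "p",
                     chrom = 1L, start_bp = 1, end_bp = 2,
                     n_snps = 10L, n_het = 0L,
                     length_kb = c(3000, 22000, 800))
  cls <- roh_length_classes(segs, c("s1", "s2"), c("p", "p"))
  expect_equal(cls$mean_count[cls$class == "[1,5)"], 0.5)
  expect_equal(cls$mean_count[cls$class == "[20,Inf)"], 0.5)
  expect_equal(sum(cls$mean_count) * 2, 2)   # the 0.8 Mb segment is excluded
})
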