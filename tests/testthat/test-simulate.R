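# small but not degenerate: a chromosome of c Morgans holds only ~4Nec-ish
# quasi-independent drift segments, so very short chromosomes at small Ne
# can lose every marker during burn-in
small_cfg <- function(seed = 1, ...) {
  sim_config(Ne = 50, n_chromosomes = 4, chrom_length_bp = 5e6,
             sample_size = 25, seed = seed, ...)
}

test_that("the simulator is a pure function of its seed", {
  s1 <- simulate_population(small_cfg(7))
  s2 <- simulate_population(small_cfg(7))
  expect_identical(s1$haplotypes$haps, s2$haplotypes$haps)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  s3 <- simulate_population(small_cfg(8))
  expect_false(identical(s1$haplotypes$haps, s3$haplotypes$haps))
})

test_that("simulated output respects the container invariants", {
  sim <- simulate_population(small_cfg(9))
  g <- sim$genotypes; h <- sim$haplotypes
  expect_silent(ldpop:::check_map_sorted(g$map))
  expect_silent(ldpop:::check_hap_consistency(h, g))
  af <- allele_frequency(g)
  expect_true(all(af$maf >= small_cfg()$min_maf_at_output))
  # heterozygosity of HWE-ish data tracks 2p(1-p); tolerance reflects the
  # modest number of quasi-independent drift segments in this fixture
  d <- heterozygosity(g)
  expect_lt(abs(d$means[["mean_Ho"]] - d$means[["mean_He"]]), 0.05)
})

test_that("simulated data round-trips through PED/MAP", {
  sim <- simulate_population(small_cfg(10))
  pd <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  write_ped_map(sim$genotypes, pd, mp)
  g2 <- read_ped_map(pd, mp)
  expect_equal(g2$calls, sim$genotypes$calls)
  expect_equal(g2$map$pos_bp, sim$genotypes$map$pos_bp)
})

test_that("without recombination chromosomes are intact founder copies", {
  cfg <- sim_config(Ne = 20, n_chromosomes = 1, chrom_length_bp = 2e6,
                    sample_size = 20, recomb_rate = 0, seed = 11,
                    candidate_factor = 5)
  sim <- simulate_population(cfg)
  H <- sim$haplotypes$haps
  # few distinct haplotypes survive drift
  expect_lte(nrow(unique(H)), 2 * 20)
  # co-segregating founder alleles: any pair with <= 3 gamete types has D' = 1
  m <- ncol(H)
  checked <- 0
  for (i in seq_len(min(m - 1, 10))) {
    for (j in (i + 1):min(m, i + 5)) {
      gam <- unique(paste(H[, i], H[, j]))
      if (length(gam) <= 3) {
        f <- haplotype_freqs_phased(sim$haplotypes, i, j)
        st <- tryCatch(ld_statistics(f), error = function(e) NULL)
        if (!is.null(st)) {
          expect_equal(st$d_prime, 1, tolerance = 1e-9)
          checked <- checked + 1
        }
      }
    }
  }
  expect_gt(checked, 0)
})

test_that("autozygosity injection hits its target coverage", {
  g <- simulate_hwe_genotypes(n_samples = 30, n_chromosomes = 6,
                              markers_per_chrom = 600, seed = 12)
  inj0 <- inject_autozygosity(g, 0, seed = 13)
  expect_identical(inj0$genotypes$calls, g$calls)
  expect_equal(nrow(inj0$truth), 0)
  expect_error(inject_autozygosity(g, 1, seed = 13), "phi")
  inj <- inject_autozygosity(g, 0.10, tract_length_mb = 5, seed = 14)
  expect_gte(mean(inj$phi >= 0.07 & inj$phi <= 0.13), 0.9)
  # tracts do not overlap within a sample
  for (s in unique(inj$truth$sample_id)) {
    tt <- inj$truth[inj$truth$sample_id == s, ]
    for (ch in unique(tt$chrom)) {
      tc <- tt[tt$chrom == ch, ]
      tc <- tc[order(tc$start_bp), ]
      if (nrow(tc) > 1)
        expect_true(all(tc$start_bp[-1] >= tc$end_bp[-nrow(tc)]))
    }
  }
  # all genotypes inside tracts are homozygous
  for (k in seq_len(min(nrow(inj$truth), 50))) {
    tr <- inj$truth[k, ]
    s <- match(tr$sample_id, g$sample_id)
    mi <- which(g$map$chrom == tr$chrom & g$map$pos_bp >= tr$start_bp &
                  g$map$pos_bp <= tr$end_bp)
    if (length(mi))
      expect_true(all(inj$genotypes$calls[s, mi] != 1L, na.rm = TRUE))
  }
})

test_that("population splits share a map and are seed-reproducible", {
  cfg <- small_cfg(15)
  sp1 <- split_populations(cfg, divergence_generations = 10)
  sp2 <- split_populations(cfg, divergence_generations = 10)
  expect_identical(sp1$popA$genotypes$calls, sp2$popA$genotypes$calls)
  expect_identical(sp1$popB$genotypes$calls, sp2$popB$genotypes$calls)
  expect_identical(sp1$popA$genotypes$map, sp1$popB$genotypes$map)
  # markers segregate in both populations
  for (p in list(sp1$popA$genotypes, sp1$popB$genotypes))
    expect_true(all(allele_frequency(p)$maf >= cfg$min_maf_at_output))
})

test_that("planted QC violations are recorded faithfully", {
  g <- simulate_hwe_genotypes(n_samples = 40, n_chromosomes = 1,
                              markers_per_chrom = 200,
                              freq_range = c(0.2, 0.8), seed = 16)
  pl <- plant_qc_violations(g, n_low_maf = 2, n_hwe = 1, n_x = 3, seed = 17)
  expect_equal(length(pl$truth$low_maf), 2)
  expect_equal(length(pl$truth$x_linked), 3)
  af <- allele_frequency(pl$genotypes)
  planted <- af[match(pl$truth$low_maf, pl$genotypes$map$id), ]
  expect_true(all(planted$maf < 0.05))
  expect_equal(sum(pl$genotypes$map$chrom == 27), 3)
  expect_error(plant_qc_violations(g, n_low_maf = 500), "not enough")
})
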