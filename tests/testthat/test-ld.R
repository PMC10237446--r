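test_that("phased counting recovers the generating haplotype frequencies", {
  haps <- rbind(matrix(c(1, 1), 40, 2, byrow = TRUE),
                matrix(c(0, 0), 40, 2, byrow = TRUE),
                matrix(c(1, 0), 10, 2, byrow = TRUE),
                matrix(c(0, 1), 10, 2, byrow = TRUE))
  h <- haplotype_matrix(haps, toy_map(2))
  f <- haplotype_freqs_phased(h, 1, 2)
  expect_equal(f$fAB, 0.4)
  expect_equal(f$fA, 0.5)
  expect_equal(f$fB, 0.5)
  expect_equal(f$n_haplotypes, 100)
  # uniform table
  u <- two_locus_freqs(0.25, 0.25, 0.25, 0.25, 100)
  expect_equal(u$fA, 0.5)
})

test_that("LD statistics reproduce hand-evaluated values", {
  st <- ld_statistics(two_locus_freqs(0.4, 0.1, 0.1, 0.4, 100))
  expect_equal(st$D, 0.15)
  expect_equal(st$r2, 0.36)
  expect_equal(st$d_prime, 0.6)
  # independence
  f0 <- two_locus_freqs(0.35 * 0.6, 0.35 * 0.4, 0.65 * 0.6, 0.65 * 0.4, 50)
  st0 <- ld_statistics(f0)
  expect_equal(st0$r2, 0, tolerance = 1e-12)
  expect_equal(st0$d_prime, 0)
  # perfect coupling
  st1 <- ld_statistics(two_locus_freqs(0.5, 0, 0, 0.5, 80))
  expect_equal(st1$r2, 1)
  expect_equal(st1$d_prime, 1)
  expect_error(ld_statistics(two_locus_freqs(0.5, 0.5, 0, 0, 10)),
               "monomorphic")
})

test_that("signed r equals brute-force Pearson correlation on all small tables", {
  # exhaustive over all two-locus tables with <= 12 haplotypes
  for (n in 2:12) {
    for (nAB in 0:n) for (nAb in 0:(n - nAB)) for (naB in 0:(n - nAB - nAb)) {
      nab <- n - nAB - nAb - naB
      a <- rep(c(1, 1, 0, 0), c(nAB, nAb, naB, nab))
      b <- rep(c(1, 0, 1, 0), c(nAB, nAb, naB, nab))
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      f <- two_locus_freqs(nAB / n, nAb / n, naB / n, nab / n, n)
      expect_equal(ld_statistics(f)$r_signed, pearson_r_oracle(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("r2 and D' are invariant to allele relabelling; signed r flips", {
  f <- two_locus_freqs(0.5, 0.2, 0.1, 0.2, 60)
  sw1 <- two_locus_freqs(0.1, 0.2, 0.5, 0.2, 60)   # swap alleles at locus 1
  sw2 <- two_locus_freqs(0.2, 0.5, 0.2, 0.1, 60)   # swap alleles at locus 2
  both <- two_locus_freqs(0.2, 0.1, 0.2, 0.5, 60)
  st <- ld_statistics(f)
  for (g in list(sw1, sw2)) {
    st2 <- ld_statistics(g)
    expect_equal(st2$r2, st$r2, tolerance = 1e-12)
    expect_equal(st2$d_prime, st$d_prime, tolerance = 1e-12)
    expect_equal(st2$r_signed, -st$r_signed, tolerance = 1e-12)
  }
  expect_equal(ld_statistics(both)$r_signed, st$r_signed, tolerance = 1e-12)
})

test_that("sample-size correction zeroes chance level, fixes r2 = 1, stays monotone", {
  expect_equal(correct_r2(1 / 50, 50), 0)
  expect_equal(correct_r2(1, 7), 1)
  expect_equal(round(correct_r2(0.36, 100), 5), 0.35354)
  r2s <- seq(0, 1, 0.05)
  expect_true(all(diff(correct_r2(r2s, 40)) > 0))
  expect_equal(correct_r2(0.3, 1e9), 0.3, tolerance = 1e-6)
  expect_error(correct_r2(0.2, 1), "haplotypes")
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  # genotypes built from haplotype pairs that never form a double heterozygote
  haps <- rbind(c(1, 1), c(1, 1),   # (2,2)
                c(0, 0), c(0, 0),   # (0,0)
                c(1, 1), c(1, 0),   # (2,1)
                c(1, 0), c(0, 0),   # (1,0)
                c(0, 1), c(0, 0))   # (0,1)
  h <- haplotype_matrix(haps, toy_map(2))
  g <- haplotypes_to_genotypes(h)
  expect_equal(sum(g$calls[, 1] == 1L & g$calls[, 2] == 1L), 0)
  fe <- haplotype_freqs_em(g, 1, 2)
  fp <- haplotype_freqs_phased(h, 1, 2)
  expect_equal(fe$fAB, fp$fAB, tolerance = 1e-9)
  expect_equal(fe$fab, fp$fab, tolerance = 1e-9)
})

test_that("EM recovers haplotype frequencies from phase-erased data", {
  set.seed(101)
  d <- multinomial_pair(c(0.4, 0.1, 0.1, 0.4), 500)
  fp <- haplotype_freqs_phased(d$h, 1, 2)
  fe <- haplotype_freqs_em(d$g, 1, 2)
  # strong-LD table: the MLE from genotypes sits close to the phased MLE
  expect_lt(abs(fe$fAB - fp$fAB), 0.01)
  # multinomial oracle: within 3 SE of the generating value
  se <- sqrt(0.4 * 0.6 / 1000)
  expect_lt(abs(fe$fAB - 0.4), 3 * se + 0.01)
})

test_that("EM and phased r2 agree on average at n = 200 diploids, MAF >= 0.05", {
  set.seed(102)
  diffs <- replicate(60, {
    repeat {
      f <- as.vector(stats::rgamma(4, 1)); f <- f / sum(f)
      pA <- f[1] + f[2]; pB <- f[1] + f[3]
      if (min(pA, 1 - pA, pB, 1 - pB) >= 0.10) break
    }
    d <- multinomial_pair(f, 200)
    af <- allele_frequency(d$g)
    if (any(af$maf < 0.05)) return(NA_real_)
    r2p <- ld_statistics(haplotype_freqs_phased(d$h, 1, 2))$r2
    r2e <- ld_statistics(haplotype_freqs_em(d$g, 1, 2))$r2
    abs(r2p - r2e)
  })
  expect_lt(mean(diffs, na.rm = TRUE), 0.02)
})

test_that("LD decay bins follow the half-open convention", {
  # two markers on one chromosome: exactly one pair in exactly one bin
  h <- haplotype_matrix(multinomial_pair(c(0.4, 0.1, 0.1, 0.4), 50)$h$haps,
                        toy_map(2, spacing = 15000))
  dec <- ld_decay(h)
  expect_equal(sum(dec$by_bin$n_pairs), 1)
  expect_equal(dec$by_bin$n_pairs[2], 1)   # 15 kb falls in [10, 20) kb
  # pair exactly at a bin edge goes to the upper bin
  h2 <- haplotype_matrix(h$haps, marker_map(c("a", "b"), 1, c(1, 20001)))
  dec2 <- ld_decay(h2)
  expect_equal(dec2$by_bin$n_pairs[3], 1)  # 20 kb -> [20, 40) kb
})

test_that("corrected mean r2 decays with distance in an equilibrium population", {
  cfg <- sim_config(Ne = 100, n_chromosomes = 8, chrom_length_bp = 5e6,
                    sample_size = 50, seed = 103)
  sim <- simulate_population(cfg)
  dec <- ld_decay(sim$haplotypes, bins = c(0, 0.05, 0.2, 0.5, 1, 2, 5) * 1e6)
  mu <- dec$by_bin$mean_r2_corrected
  expect_true(all(diff(mu) < 0.05))        # non-increasing within noise
  expect_gt(mu[1], mu[length(mu)])
  # Sved-style magnitude check in the 1-2 cM bin (c ~ 0.015 M)
  expect_lt(abs(mu[5] - expected_r2(100, 0.015)), 0.12)
})

test_that("genotype (EM) LD path approximates the phased path on real structure", {
  cfg <- sim_config(Ne = 60, n_chromosomes = 2, chrom_length_bp = 5e6,
                    sample_size = 60, seed = 104)
  sim <- simulate_population(cfg)
  dp <- ld_decay(sim$haplotypes, bins = c(0, 0.5, 2) * 1e6)
  dg <- ld_decay(sim$genotypes, bins = c(0, 0.5, 2) * 1e6)
  expect_equal(dg$by_bin$n_pairs, dp$by_bin$n_pairs)
  expect_lt(max(abs(dg$by_bin$mean_r2 - dp$by_bin$mean_r2), na.rm = TRUE), 0.03)
})
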