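# shared fixture builders and independent oracles

# quick marker map on one chromosome
toy_map <- function(n, chrom = 1, spacing = 1e4, start = 1e4) {
  marker_map(sprintf("c%dm%d", chrom, seq_len(n)), chrom,
             seq(start, by = spacing, length.out = n))
}

# genotype matrix from a plain integer matrix (samples x markers)
toy_geno <- function(calls, chrom = 1, spacing = 1e4, population = "pop1") {
  calls <- as.matrix(calls)
  genotype_matrix(calls, toy_map(ncol(calls), chrom, spacing),
                  population = population)
}

# haplotype pair sampled from four-gamete frequencies (AB, Ab, aB, ab)
multinomial_pair <- function(freqs, n_diploid = 200) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  haps <- sample(4, 2 * n_diploid, replace = TRUE, prob = freqs)
  a <- as.integer(haps %in% c(1, 2))
  b <- as.integer(haps %in% c(1, 3))
  map <- marker_map(c("mA", "mB"), c(1, 1), c(1e4, 2e4))
  h <- haplotype_matrix(cbind(a, b), map)
  list(h = h, g = haplotypes_to_genotypes(h))
}

# independent oracle: Pearson correlation of the two binary haplotype columns
pearson_r_oracle <- function(a, b) {
  suppressWarnings(stats::cor(a, b))
}

# independent oracle: exact HWE p-value by direct enumeration with choose()
hwe_brute <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h)
    choose(n, h) * choose(n - h, (nA - h) / 2) * 2^h, numeric(1))
  w <- w / sum(w)
  obs <- which(hets == nAB)
  min(1, sum(w[w <= w[obs] * (1 + 1e-7)]))
}

# HWE genotypes at a single shared allele frequency
hwe_geno <- function(n_samples, n_markers, p = 0.3, chrom = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(rbinom(n_samples * n_markers, 2, p), n_samples, n_markers)
  toy_geno(calls, chrom = chrom)
}
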