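#' QC configuration
#'
#' Thresholds for the sequential quality-control cascade.  Defaults follow
#' common SNP-array practice: drop animals with more than 10% missing
#' genotypes, then SNPs with MAF below 0.05, call rate below 95%, or strong
#' Hardy-Weinberg deviation at the Bonferroni-corrected per-test level
#' (0.05 experiment-wise over the pre-QC SNP count), then SNPs of unknown
#' position and SNPs on sex chromosomes.
#'
#' @param max_sample_missing maximum tolerated per-sample missing fraction.
#' @param min_maf minimum minor-allele frequency.
#' @param min_snp_call_rate minimum per-SNP call rate.
#' @param experimentwise_alpha experiment-wise type-I level for HWE.
#' @param n_tests_for_bonferroni number of tests for the Bonferroni
#'   correction; `NULL` (default) uses the pre-QC SNP count.
#' @param drop_unknown_position drop markers with chromosome label 0?
#' @param drop_sex_chromosomes drop markers with chromosome label > 26?
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_sample_missing = 0.10, min_maf = 0.05,
                      min_snp_call_rate = 0.95, experimentwise_alpha = 0.05,
                      n_tests_for_bonferroni = NULL,
                      drop_unknown_position = TRUE, drop_sex_chromosomes = TRUE) {
  fr <- c(max_sample_missing, min_maf, min_snp_call_rate, experimentwise_alpha)
  if (any(fr < 0 | fr > 1)) stop("QC fractions must lie in [0, 1]")
  structure(list(max_sample_missing = max_sample_missing, min_maf = min_maf,
                 min_snp_call_rate = min_snp_call_rate,
                 experimentwise_alpha = experimentwise_alpha,
                 n_tests_for_bonferroni = n_tests_for_bonferroni,
                 drop_unknown_position = drop_unknown_position,
                 drop_sex_chromosomes = drop_sex_chromosomes),
            class = "qc_config")
}

#' B-allele frequency and MAF per marker
#'
#' `freq = (n_het + 2 n_homB) / (2 n_nonmissing)`; `maf = min(freq, 1-freq)`.
#' Markers with no non-missing call get `NA` frequency (they cannot pass the
#' call-rate filter anyway).
#'
#' @param g a `genotype_matrix`.
#' @return data.frame `id, n_called, freqB, maf, call_rate`.
#' @export
allele_frequency <- function(g) {
  nb <- colSums(g$calls, na.rm = TRUE)
  nc <- colSums(!is.na(g$calls))
  freq <- ifelse(nc > 0, nb / (2 * nc), NA_real_)
  data.frame(id = g$map$id, n_called = nc, freqB = freq,
             maf = pmin(freq, 1 - freq),
             call_rate = nc / n_samples(g),
             stringsAsFactors = FALSE)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic SNP: given the observed allele
#' counts, the two-sided p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count.  Monomorphic markers return p = 1.  Computed with log-factorials;
#' stable up to array-scale sample sizes.
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("need at least one individual")
  nA <- 2 * n_AA + n_AB            # count of the rarer allele's complement ok
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  # heterozygote count shares parity with the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_het = h | allele counts) up to a common constant:
  #   n! / (nAA! nAB! nBB!) * 2^h  with nAB = h, nAA = (nA - h)/2 ...
  nr <- (rare - hets) / 2
  nc_ <- (max(nA, nB) - rare) / 2 + nr
  logp <- hets * log(2) - lfactorial(hets) - lfactorial(nr) - lfactorial(nc_)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- which(hets == n_AB)
  if (length(obs) == 0) stop("impossible heterozygote count for allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

#' Bonferroni per-test threshold
#'
#' `alpha / n_tests`; with the 0.05 experiment-wise level over a 50,000-SNP
#' array this gives the conventional 1e-6 per-SNP HWE threshold.
#'
#' @param alpha experiment-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Run the QC cascade
#'
#' Sequential filters, each applied to the survivors of the previous step:
#' (1) samples with missing fraction above `max_sample_missing`;
#' (2) SNPs with MAF below `min_maf`; (3) SNPs with call rate below
#' `min_snp_call_rate`; (4) SNPs with exact-HWE p below the Bonferroni
#' threshold, tested within each population (a SNP is removed if it
#' violates in any population); (5) SNPs of unknown position; (6) SNPs on
#' sex chromosomes.  Per-marker statistics are recomputed once after the
#' sample-removal step.  Counts in the report are sequential removals, not
#' marginal ones, so they sum with the remainder to the input size.
#'
#' @param g a `genotype_matrix`.
#' @param cfg a [qc_config()].
#' @return list of class `qc_result` with elements `genotypes` (filtered
#'   matrix) and `report` (data.frame of per-step removal counts).
#' @export
run_qc <- function(g, cfg = qc_config()) {
  n0_samp <- n_samples(g); n0_snp <- n_markers(g)
  n_tests <- if (is.null(cfg$n_tests_for_bonferroni)) n0_snp else
    cfg$n_tests_for_bonferroni
  thr <- if (n_tests >= 1) bonferroni_threshold(cfg$experimentwise_alpha, n_tests)
         else 0

  # step 1: sample call rate
  miss_frac <- rowMeans(is.na(g$calls))
  keep_s <- miss_frac <= cfg$max_sample_missing
  n_drop_samp <- sum(!keep_s)
  g <- subset_genotypes(g, samples = keep_s)

  stats <- allele_frequency(g)
  alive <- rep(TRUE, n_markers(g))

  # step 2: MAF
  fail_maf <- alive & (is.na(stats$maf) | stats$maf < cfg$min_maf)
  # all-missing markers are attributed to the call-rate step, not MAF
  fail_maf[is.na(stats$maf)] <- FALSE
  n_maf <- sum(fail_maf); alive <- alive & !fail_maf

  # step 3: call rate
  fail_cr <- alive & stats$call_rate < cfg$min_snp_call_rate
  n_cr <- sum(fail_cr); alive <- alive & !fail_cr

  # step 4: HWE within population
  fail_hwe <- rep(FALSE, n_markers(g))
  if (any(alive) && n_samples(g) > 0) {
    idx <- which(alive)
    pops <- unique(g$population)
    pmin_ <- rep(1, length(idx))
    for (pop in pops) {
      rows <- g$population == pop
      sub <- g$calls[rows, idx, drop = FALSE]
      nAA <- colSums(sub == 0L, na.rm = TRUE)
      nAB <- colSums(sub == 1L, na.rm = TRUE)
      nBB <- colSums(sub == 2L, na.rm = TRUE)
      pv <- vapply(seq_along(idx), function(k) {
        if (nAA[k] + nAB[k] + nBB[k] < 1) return(1)
        hwe_exact_test(nAA[k], nAB[k], nBB[k])
      }, numeric(1))
      pmin_ <- pmin(pmin_, pv)
    }
    fail_hwe[idx] <- pmin_ < thr
  }
  n_hwe <- sum(fail_hwe); alive <- alive & !fail_hwe

  # step 5: unknown position
  fail_unk <- if (cfg$drop_unknown_position) alive & g$map$chrom == 0L
              else rep(FALSE, n_markers(g))
  n_unk <- sum(fail_unk); alive <- alive & !fail_unk

  # step 6: sex chromosomes
  fail_sex <- if (cfg$drop_sex_chromosomes) alive & g$map$chrom > 26L
              else rep(FALSE, n_markers(g))
  n_sex <- sum(fail_sex); alive <- alive & !fail_sex

  out <- subset_genotypes(g, markers = alive)
  report <- data.frame(
    step = c("animals_low_call_rate", "snps_low_maf", "snps_low_call_rate",
             "snps_hwe_deviation", "snps_unknown_position",
             "snps_sex_chromosome", "animals_remaining", "snps_remaining"),
    removed = c(n_drop_samp, n_maf, n_cr, n_hwe, n_unk, n_sex,
                NA_integer_, NA_integer_),
    remaining = c(NA, NA, NA, NA, NA, NA, n_samples(out), n_markers(out)),
    stringsAsFactors = FALSE)
  structure(list(genotypes = out, report = report,
                 hwe_threshold = thr,
                 initial = c(samples = n0_samp, snps = n0_snp)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC cascade (", x$initial["samples"], "animals x", x$initial["snps"],
      "SNPs in )\n")
  r <- x$report
  for (i in 1:6)
    cat(sprintf("  %-24s removed %d\n", r$step[i], r$removed[i]))
  cat(sprintf("  remaining: %d animals x %d SNPs (HWE threshold %.3g)\n",
              r$remaining[7], r$remaining[8], x$hwe_threshold))
  invisible(x)
}

#' Heterozygosity, MAF and marker-spacing summary
#'
#' Per SNP: observed heterozygosity `Ho = n_het / n_called` and expected
#' heterozygosity `He = 2 p (1 - p)`.  Genome-wide values are unweighted
#' means (with SD) over SNPs; marker spacing is the mean successive-position
#' difference within each chromosome, in kb.
#'
#' @param g a post-QC `genotype_matrix`.
#' @return list of class `diversity_summary`: `per_snp` (data.frame),
#'   `means` (named vector), `spacing_kb` (per chromosome + overall mean).
#' @export
heterozygosity <- function(g) {
  af <- allele_frequency(g)
  nhet <- colSums(g$calls == 1L, na.rm = TRUE)
  ho <- ifelse(af$n_called > 0, nhet / af$n_called, NA_real_)
  he <- 2 * af$freqB * (1 - af$freqB)
  per_snp <- data.frame(id = g$map$id, chrom = g$map$chrom,
                        pos_bp = g$map$pos_bp, maf = af$maf, Ho = ho, He = he,
                        stringsAsFactors = FALSE)
  sp <- vapply(split(g$map$pos_bp, g$map$chrom), function(p)
    if (length(p) > 1) mean(diff(p)) / 1000 else NA_real_, numeric(1))
  means <- c(mean_Ho = mean(ho, na.rm = TRUE), sd_Ho = sd(ho, na.rm = TRUE),
             mean_He = mean(he, na.rm = TRUE), sd_He = sd(he, na.rm = TRUE),
             mean_maf = mean(af$maf, na.rm = TRUE),
             mean_spacing_kb = mean(sp, na.rm = TRUE))
  structure(list(per_snp = per_snp, means = means, spacing_kb = sp),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  m <- x$means
  cat(sprintf("diversity: Ho %.4f +- %.4f | He %.4f +- %.4f | MAF %.4f | spacing %.1f kb\n",
              m["mean_Ho"], m["sd_Ho"], m["mean_He"], m["sd_He"],
              m["mean_maf"], m["mean_spacing_kb"]))
  invisible(x)
}

#' Genotype principal component analysis
#'
#' Markers are centred by `2p` and scaled by `sqrt(2p(1-p))` (monomorphic
#' markers dropped); missing calls are mean-imputed (zero after centring).
#' Axes are the left singular vectors of the standardized matrix, i.e.
#' eigenvectors of the sample-by-sample covariance; per-axis variance
#' fractions come from the eigenvalues.
#'
#' @param g a `genotype_matrix` with >= 2 samples and >= 2 markers.
#' @param n_axes number of leading axes to return.
#' @return list of class `genotype_pca`: `scores` (samples x axes),
#'   `var_fraction`, `sample_id`, `population`.
#' @export
pca_genotypes <- function(g, n_axes = 10) {
  if (n_samples(g) < 2 || n_markers(g) < 2)
    stop("PCA needs at least 2 samples and 2 markers")
  af <- allele_frequency(g)
  keep <- !is.na(af$freqB) & af$freqB > 0 & af$freqB < 1
  if (sum(keep) < 1) stop("no polymorphic markers for PCA")
  p <- af$freqB[keep]
  x <- g$calls[, keep, drop = FALSE]
  xs <- sweep(x, 2, 2 * p, "-")
  xs <- sweep(xs, 2, sqrt(2 * p * (1 - p)), "/")
  xs[is.na(xs)] <- 0                       # mean imputation
  if (all(abs(xs) < 1e-12)) stop("all samples identical: PCA undefined")
  sv <- svd(xs)
  ev <- sv$d^2
  k <- min(n_axes, sum(ev > 1e-9 * ev[1]), n_samples(g) - 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- g$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, var_fraction = ev[seq_len(k)] / sum(ev),
                 sample_id = g$sample_id, population = g$population),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype PCA:", nrow(x$scores), "samples,", ncol(x$scores), "axes\n")
  vf <- x$var_fraction[seq_len(min(5, length(x$var_fraction)))]
  cat("  variance fractions:", paste(sprintf("%.3f", vf), collapse = " "), "\n")
  invisible(x)
}
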