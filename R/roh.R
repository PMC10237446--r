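#' ROH scanning parameters
#'
#' PLINK-style sliding-window parameters.  Defaults mirror the common
#' array-density settings: 20-SNP windows allowing at most 1 heterozygous
#' and 5 missing calls, window hit-rate threshold 0.05, minimum run length
#' 10 kb, maximum density 1000 kb/SNP, maximum inter-SNP gap 1000 kb.
#' `min_snp_count` is the minimum number of SNPs in a run; when `NULL` it
#' should be set from [min_roh_snps()] (false-positive-calibrated).
#'
#' @param window_snp SNPs per scanning window.
#' @param window_het_max maximum heterozygous calls per hit window (and per
#'   final run).
#' @param window_missing_max maximum missing calls per hit window.
#' @param window_hit_threshold minimum fraction of hit windows covering a
#'   SNP for it to be run-eligible.
#' @param min_length_kb minimum run length (kb).
#' @param density_kb_per_snp maximum kb per SNP within a run.
#' @param max_gap_kb maximum gap between consecutive run SNPs (kb).
#' @param min_snp_count minimum SNPs per run (`NULL` = 1; normally Eq-style
#'   calibrated via [min_roh_snps()]).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 20, window_het_max = 1,
                       window_missing_max = 5, window_hit_threshold = 0.05,
                       min_length_kb = 10, density_kb_per_snp = 1000,
                       max_gap_kb = 1000, min_snp_count = NULL) {
  v <- c(window_snp, window_het_max + 1, window_missing_max + 1,
         window_hit_threshold, min_length_kb, density_kb_per_snp, max_gap_kb)
  if (any(v <= 0)) stop("ROH parameters must be positive")
  structure(list(window_snp = as.integer(window_snp),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_threshold = window_hit_threshold,
                 min_length_kb = min_length_kb,
                 density_kb_per_snp = density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 min_snp_count = if (is.null(min_snp_count)) 1L
                                 else as.integer(min_snp_count)),
            class = "roh_params")
}

#' Minimum SNP count for an ROH
#'
#' False-positive calibration: the smallest l such that a chance run of l
#' homozygous SNPs is expected fewer than `alpha` times over all SNPs and
#' individuals: `l = ceiling( ln(alpha / (n_snps * n_individuals)) /
#' ln(1 - mean_het) )`.
#'
#' @param n_snps genotyped SNPs per individual.
#' @param n_individuals number of individuals.
#' @param alpha tolerated number of false-positive ROH (default 0.05).
#' @param mean_het mean SNP heterozygosity, in (0, 1).
#' @return integer minimum SNP count (>= 1).
#' @export
min_roh_snps <- function(n_snps, n_individuals, alpha = 0.05, mean_het) {
  if (mean_het <= 0 || mean_het >= 1) stop("mean_het must lie in (0, 1)")
  if (n_snps < 1 || n_individuals < 1) stop("counts must be >= 1")
  max(1L, as.integer(ceiling(log(alpha / (n_snps * n_individuals)) /
                               log(1 - mean_het))))
}

# scan one sample on one chromosome; returns data.frame of runs
scan_roh_chrom <- function(x, pos, p) {
  L <- length(x)
  if (L < p$window_snp) return(NULL)
  het <- as.integer(!is.na(x) & x == 1L)
  mis <- as.integer(is.na(x))
  w <- p$window_snp
  nw <- L - w + 1L
  csh <- c(0L, cumsum(het)); csm <- c(0L, cumsum(mis))
  hsum <- csh[(w + 1):(L + 1)] - csh[1:nw]
  msum <- csm[(w + 1):(L + 1)] - csm[1:nw]
  hit <- as.integer(hsum <= p$window_het_max & msum <= p$window_missing_max)
  # SNP i is covered by windows starting in [max(1, i-w+1), min(i, nw)]
  csx <- c(0L, cumsum(hit))
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L); hi <- pmin(i, nw)
  nwin <- pmax(hi - lo + 1L, 0L)
  nhit <- ifelse(hi >= lo, csx[hi + 1L] - csx[lo], 0L)
  eligible <- nwin > 0L & nhit / pmax(nwin, 1L) >= p$window_hit_threshold
  if (!any(eligible)) return(NULL)
  # maximal runs of eligible SNPs
  r <- rle(eligible)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  out <- list()
  hom <- !is.na(x) & x != 1L
  for (k in seq_len(nrow(runs))) {
    s <- runs[k, 1]; e <- runs[k, 2]
    # trim to homozygous non-missing ends
    while (s <= e && !hom[s]) s <- s + 1L
    while (e >= s && !hom[e]) e <- e - 1L
    if (s > e) next
    # split at gaps larger than max_gap_kb
    seg_starts <- s
    if (e > s) {
      gaps <- which(diff(pos[s:e]) > p$max_gap_kb * 1000)
      seg_starts <- c(s, s + gaps)
      seg_ends <- c(s + gaps - 1L, e)
    } else seg_ends <- e
    for (q in seq_along(seg_starts)) {
      a <- seg_starts[q]; b <- seg_ends[q]
      while (a <= b && !hom[a]) a <- a + 1L
      while (b >= a && !hom[b]) b <- b - 1L
      if (a > b) next
      # enforce the per-run heterozygote budget by shrinking to the longest
      # (bp) sub-run with <= window_het_max hets, not by discarding the run
      hpos <- a - 1L + which(het[a:b] == 1L)
      if (length(hpos) > p$window_het_max) {
        Hm <- p$window_het_max
        bounds <- c(a - 1L, hpos, b + 1L)   # sub-run k: (bounds[k], bounds[k+Hm+1])
        best <- NULL; best_len <- -1
        for (k in seq_len(length(bounds) - Hm - 1L)) {
          aa <- bounds[k] + 1L; bb <- bounds[k + Hm + 1L] - 1L
          while (aa <= bb && !hom[aa]) aa <- aa + 1L
          while (bb >= aa && !hom[bb]) bb <- bb - 1L
          if (aa > bb) next
          if (pos[bb] - pos[aa] > best_len) {
            best <- c(aa, bb); best_len <- pos[bb] - pos[aa]
          }
        }
        if (is.null(best)) next
        a <- best[1]; b <- best[2]
      }
      nsnp <- b - a + 1L
      len_kb <- (pos[b] - pos[a]) / 1000
      nhet <- sum(het[a:b])
      dens_ok <- len_kb / nsnp <= p$density_kb_per_snp
      if (nsnp >= p$min_snp_count && len_kb >= p$min_length_kb && dens_ok)
        out[[length(out) + 1]] <- data.frame(
          start_idx = a, end_idx = b, start_bp = pos[a], end_bp = pos[b],
          n_snps = nsnp, n_het = nhet, length_kb = len_kb)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Detect runs of homozygosity
#'
#' PLINK-style scan, per sample and chromosome: a window of `window_snp`
#' SNPs "hits" if it has at most `window_het_max` heterozygous and
#' `window_missing_max` missing calls; a SNP is run-eligible when the
#' fraction of hit windows covering it reaches `window_hit_threshold`;
#' maximal eligible runs are trimmed to homozygous end calls, split at gaps
#' above `max_gap_kb`, shrunk (when needed) to the longest sub-run holding
#' at most `window_het_max` heterozygous calls, and filtered on SNP count,
#' length and SNP density.  Every reported segment therefore respects the
#' heterozygote budget.  Chromosomes with fewer SNPs than one window are
#' skipped (with a message).
#'
#' @param g a post-QC `genotype_matrix`.
#' @param params a [roh_params()].
#' @param verbose emit skip notices?
#' @return data.frame of class `roh_segments`:
#'   `sample_id, population, chrom, start_bp, end_bp, n_snps, n_het, length_kb`.
#' @export
detect_roh <- function(g, params = roh_params(), verbose = FALSE) {
  out <- list()
  chroms <- unique(g$map$chrom)
  for (ch in chroms) {
    mi <- which(g$map$chrom == ch)
    if (length(mi) < params$window_snp) {
      if (verbose) message("chromosome ", ch, " has fewer than ",
                           params$window_snp, " SNPs; skipped")
      next
    }
    pos <- g$map$pos_bp[mi]
    for (s in seq_len(n_samples(g))) {
      runs <- scan_roh_chrom(g$calls[s, mi], pos, params)
      if (is.null(runs)) next
      out[[length(out) + 1]] <- data.frame(
        sample_id = g$sample_id[s], population = g$population[s],
        chrom = ch, start_bp = runs$start_bp, end_bp = runs$end_bp,
        n_snps = runs$n_snps, n_het = runs$n_het, length_kb = runs$length_kb,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), population = character(),
               chrom = integer(), start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), n_het = integer(), length_kb = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$sample_id, res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

#' Genomic inbreeding from ROH coverage
#'
#' `F_ROH = sum of ROH lengths / total autosome length`, counting only
#' segments of at least `min_segment_mb` (the conventional 1 Mb floor).
#' A per-chromosome variant divides each chromosome's ROH total by that
#' chromosome's span.
#'
#' @param segments [detect_roh()] output.
#' @param sample_id vector of all sample ids (so ROH-free samples get 0).
#' @param l_auto_bp total autosome length in bp.
#' @param min_segment_mb segment length floor in Mb.
#' @param chrom_lengths_bp optional named vector of per-chromosome spans for
#'   the per-chromosome variant.
#' @return data.frame `sample_id, F_ROH` (plus `F_ROH_chr<k>` columns when
#'   `chrom_lengths_bp` is given).
#' @export
f_roh <- function(segments, sample_id, l_auto_bp, min_segment_mb = 1,
                  chrom_lengths_bp = NULL) {
  if (l_auto_bp <= 0) stop("l_auto_bp must be positive")
  seg <- segments[segments$length_kb >= min_segment_mb * 1000, , drop = FALSE]
  tot <- tapply(seg$length_kb * 1000, factor(seg$sample_id, levels = sample_id),
                sum, default = 0)
  out <- data.frame(sample_id = sample_id,
                    F_ROH = as.numeric(tot) / l_auto_bp,
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths_bp)) {
    for (ch in names(chrom_lengths_bp)) {
      s2 <- seg[seg$chrom == as.integer(ch), , drop = FALSE]
      t2 <- tapply(s2$length_kb * 1000,
                   factor(s2$sample_id, levels = sample_id), sum, default = 0)
      out[[paste0("F_ROH_chr", ch)]] <- as.numeric(t2) / chrom_lengths_bp[[ch]]
    }
  }
  out
}

#' GRM-family genomic inbreeding estimators
#'
#' Per individual, averaged over usable loci (non-missing, 0 < p < 1), with
#' x the B-allele count and p the within-population B-allele frequency:
#' \itemize{
#'   \item `Fhat1` (diagonal of the GRM minus 1):
#'     `mean[ (x - 2p)^2 / (2p(1-p)) ] - 1`
#'   \item `Fhat2` (excess homozygosity):
#'     `1 - sum[ x(2-x) ] / sum[ 2p(1-p) ]`
#'   \item `Fhat3` (correlation of uniting gametes):
#'     `mean[ (x^2 - (1+2p)x + 2p^2) / (2p(1-p)) ]`
#' }
#' Frequencies are computed within each population of `g` separately.
#'
#' @param g a post-QC `genotype_matrix`.
#' @return data.frame `sample_id, population, Fhat1, Fhat2, Fhat3`.
#' @export
grm_inbreeding <- function(g) {
  out <- data.frame(sample_id = g$sample_id, population = g$population,
                    Fhat1 = NA_real_, Fhat2 = NA_real_, Fhat3 = NA_real_,
                    stringsAsFactors = FALSE)
  for (pop in unique(g$population)) {
    rows <- which(g$population == pop)
    x <- g$calls[rows, , drop = FALSE]
    p <- colMeans(x, na.rm = TRUE) / 2
    use <- !is.na(p) & p > 0 & p < 1
    if (!any(use)) next
    x <- x[, use, drop = FALSE]
    p <- p[use]
    het_exp <- 2 * p * (1 - p)
    for (k in seq_along(rows)) {
      xi <- x[k, ]
      ok <- !is.na(xi)
      if (!any(ok)) next
      xv <- xi[ok]; pv <- p[ok]; hv <- het_exp[ok]
      out$Fhat1[rows[k]] <- mean((xv - 2 * pv)^2 / hv) - 1
      out$Fhat2[rows[k]] <- 1 - sum(xv * (2 - xv)) / sum(hv)
      out$Fhat3[rows[k]] <- mean((xv^2 - (1 + 2 * pv) * xv + 2 * pv^2) / hv)
    }
  }
  out
}

#' ROH length-class summary
#'
#' Mean per-individual ROH count and total length per length class, per
#' population.  Default classes: [1,5), [5,10), [10,15), [15,20), >= 20 Mb;
#' segments below the first class floor are excluded.
#'
#' @param segments [detect_roh()] output (with `population` column).
#' @param sample_id all sample ids.
#' @param population population label per sample.
#' @param class_mb lower class edges in Mb (last class is open-ended).
#' @return data.frame `population, class, mean_count, mean_total_mb`.
#' @export
roh_length_classes <- function(segments, sample_id, population,
                               class_mb = c(1, 5, 10, 15, 20)) {
  edges <- c(class_mb, Inf)
  labs <- paste0("[", class_mb, ",", c(class_mb[-1], "Inf"), ")")
  len_mb <- segments$length_kb / 1000
  cls <- cut(len_mb, edges, right = FALSE, labels = labs)
  keep <- !is.na(cls)
  seg <- segments[keep, , drop = FALSE]; cls <- cls[keep]
  out <- list()
  for (pop in unique(population)) {
    ids <- sample_id[population == pop]
    srows <- seg$sample_id %in% ids
    for (lv in labs) {
      sel <- srows & cls == lv
      out[[length(out) + 1]] <- data.frame(
        population = pop, class = lv,
        mean_count = sum(sel) / length(ids),
        mean_total_mb = sum(len_mb[keep][sel]) / length(ids),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
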