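#' Two-locus frequency container
#'
#' Allele and haplotype frequencies at a marker pair, with the haplotype
#' count behind them.  Margins are checked for consistency.
#'
#' @param fAB,fAb,faB,fab haplotype frequencies (A/a = first locus alleles,
#'   B/b = second locus; capital = B-allele of the map orientation).
#' @param n_haplotypes number of haplotypes the frequencies are based on.
#' @return list of class `two_locus_freqs` with allele margins filled in.
#' @export
two_locus_freqs <- function(fAB, fAb, faB, fab, n_haplotypes) {
  tot <- fAB + fAb + faB + fab
  if (abs(tot - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  f <- list(fAB = fAB, fAb = fAb, faB = faB, fab = fab,
            fA = fAB + fAb, fa = faB + fab,
            fB = fAB + faB, fb = fAb + fab,
            n_haplotypes = n_haplotypes)
  structure(f, class = "two_locus_freqs")
}

#' Haplotype frequencies from phased data by direct counting
#'
#' @param h a `haplotype_matrix`.
#' @param i,j marker indices (distinct, same chromosome).
#' @return a [two_locus_freqs()].
#' @export
haplotype_freqs_phased <- function(h, i, j) {
  if (i == j) stop("markers must be distinct")
  a <- h$haps[, i]; b <- h$haps[, j]
  n <- length(a)
  if (n == 0) stop("no haplotypes to count")
  # "A" is the B-allele (coded 1) at locus i, "B" the B-allele at locus j
  nAB <- sum(a == 1L & b == 1L); nAb <- sum(a == 1L & b == 0L)
  naB <- sum(a == 0L & b == 1L); nab <- sum(a == 0L & b == 0L)
  two_locus_freqs(nAB / n, nAb / n, naB / n, nab / n, n)
}

#' Haplotype frequencies from unphased genotypes by two-locus EM
#'
#' Maximum-likelihood haplotype frequencies under the standard two-locus EM:
#' all genotype combinations except the double heterozygote determine their
#' haplotypes; the double heterozygote's coupling/repulsion split is the
#' E-step expectation under the current frequencies.  Initialization is at
#' linkage equilibrium (deterministic).  Samples missing at either marker
#' are excluded.
#'
#' @param g a `genotype_matrix`.
#' @param i,j marker indices.
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a [two_locus_freqs()] with `n_haplotypes = 2 * n_samples_used`.
#' @export
haplotype_freqs_em <- function(g, i, j, tol = 1e-10, max_iter = 1000) {
  x <- g$calls[, i]; y <- g$calls[, j]
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  n <- length(x)
  if (n == 0) stop("no samples called at both markers")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("both markers must be polymorphic among jointly called samples")
  # genotype combination counts; cell [x+1, y+1]
  tab <- matrix(0, 3, 3)
  for (k in seq_len(n)) tab[x[k] + 1L, y[k] + 1L] <- tab[x[k] + 1L, y[k] + 1L] + 1
  nhap <- 2 * n
  pA <- mean(x) / 2; pB <- mean(y) / 2
  # counts of unambiguous haplotypes (coefficients on the 9 cells)
  # cell (gx, gy): contributes known haplotypes except gx==1 && gy==1
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  base <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  ndh <- tab[2, 2]
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between coupling (AB/ab) and repulsion
    pc <- f["AB"] * f["ab"]; pr <- f["Ab"] * f["aB"]
    w <- if (pc + pr > 0) pc / (pc + pr) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    fnew <- cnt / nhap
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol)
      return(two_locus_freqs(f[["AB"]], f[["Ab"]], f[["aB"]], f[["ab"]], nhap))
  }
  stop("EM did not converge in ", max_iter,
       " iterations (last freqs: ", paste(signif(f, 6), collapse = ", "), ")")
}

#' Pairwise LD statistics from two-locus frequencies
#'
#' `D = fAB fab - fAb faB`; signed `r = D / sqrt(fA fa fB fb)`; `r2 = r^2`;
#' `D' = |D| / Dmax` with `Dmax = min(fA fb, fa fB)` when `D > 0`, else
#' `min(fA fB, fa fb)`; `D = 0` gives `D' = 0`.
#'
#' @param f a [two_locus_freqs()].
#' @return named list `r_signed, r2, d_prime, D`.
#' @export
ld_statistics <- function(f) {
  if (min(f$fA, f$fa, f$fB, f$fb) <= 0)
    stop("LD undefined: monomorphic margin")
  D <- f$fAB * f$fab - f$fAb * f$faB
  r <- D / sqrt(f$fA * f$fa * f$fB * f$fb)
  dmax <- if (D > 0) min(f$fA * f$fb, f$fa * f$fB)
          else if (D < 0) min(f$fA * f$fB, f$fa * f$fb)
          else 1
  list(r_signed = r, r2 = r * r,
       d_prime = if (D == 0) 0 else abs(D) / dmax, D = D)
}

#' Sample-size correction of r-squared
#'
#' `r2_corrected = (r2 - 1/n) / (1 - 1/n)` with `n` the number of haplotypes
#' in the sample; subtracts the chance-level correlation expected from a
#' finite sample.  Negative corrected values are retained (not clipped).
#'
#' @param r2_computed raw r-squared value(s).
#' @param n_haplotypes haplotype count (>= 2).
#' @return corrected r-squared (vectorized).
#' @export
correct_r2 <- function(r2_computed, n_haplotypes) {
  if (any(n_haplotypes < 2)) stop("need at least 2 haplotypes")
  (r2_computed - 1 / n_haplotypes) / (1 - 1 / n_haplotypes)
}

#' Default physical distance bins for LD decay (bp)
#'
#' Half-open `[lo, hi)` bins in Mb:
#' 0-0.01, 0.01-0.02, 0.02-0.04, 0.04-0.06, 0.06-0.08, 0.08-0.1, 0.1-0.2,
#' 0.2-0.5, 0.5-1, 1-2, 2-5, 5-10, 10-20.
#' @return numeric vector of bin edges in bp.
#' @export
ld_distance_bins <- function() {
  c(0, 0.01, 0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20) * 1e6
}

# all intra-chromosomal pair LD values within max distance, as a data.frame.
# source: haplotype_matrix (direct counting, vectorized via cor()) or
# genotype_matrix (per-pair EM).  Markers missing in > `max_missing` of
# samples are skipped on the genotype path.
ld_pair_table <- function(source, max_pair_distance = 20e6, max_missing = 0.5) {
  phased <- inherits(source, "haplotype_matrix")
  map <- source$map
  out <- vector("list", 0)
  for (ch in unique(map$chrom)) {
    mi <- which(map$chrom == ch)
    if (length(mi) < 2) next
    pos <- map$pos_bp[mi]
    if (phased) {
      H <- source$haps[, mi, drop = FALSE]
      p <- colMeans(H)
      poly <- p > 0 & p < 1
      H <- H[, poly, drop = FALSE]; pos2 <- pos[poly]; ids <- mi[poly]
      if (length(pos2) < 2) next
      cc <- suppressWarnings(cor(H))
      n <- nrow(H)
      pr <- which(upper.tri(cc), arr.ind = TRUE)
      d <- pos2[pr[, 2]] - pos2[pr[, 1]]
      keep <- d > 0 & d < max_pair_distance
      pr <- pr[keep, , drop = FALSE]; d <- d[keep]
      if (nrow(pr) == 0) next
      r <- cc[pr]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, i = ids[pr[, 1]], j = ids[pr[, 2]],
        adjacent = pr[, 2] == pr[, 1] + 1L,
        distance_bp = d, r_signed = r, r2 = r * r,
        n_haplotypes = n)
    } else {
      calls <- source$calls[, mi, drop = FALSE]
      missfrac <- colMeans(is.na(calls))
      af <- colMeans(calls, na.rm = TRUE) / 2
      usable <- missfrac <= max_missing & !is.na(af) & af > 0 & af < 1
      uid <- which(usable)
      if (length(uid) < 2) next
      rows <- list()
      for (a in seq_len(length(uid) - 1)) {
        for (b in (a + 1):length(uid)) {
          d <- pos[uid[b]] - pos[uid[a]]
          if (d >= max_pair_distance) break
          fr <- tryCatch(haplotype_freqs_em(source, mi[uid[a]], mi[uid[b]]),
                         error = function(e) NULL)
          if (is.null(fr)) next
          st <- tryCatch(ld_statistics(fr), error = function(e) NULL)
          if (is.null(st)) next
          rows[[length(rows) + 1]] <- data.frame(
            chrom = ch, i = mi[uid[a]], j = mi[uid[b]],
            adjacent = b == a + 1L, distance_bp = d,
            r_signed = st$r_signed, r2 = st$r2,
            n_haplotypes = fr$n_haplotypes)
        }
      }
      if (length(rows)) out[[length(out) + 1]] <- do.call(rbind, rows)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), i = integer(), j = integer(),
                      adjacent = logical(), distance_bp = numeric(),
                      r_signed = numeric(), r2 = numeric(),
                      n_haplotypes = integer()))
  do.call(rbind, out)
}

#' LD decay over distance bins
#'
#' Computes all intra-chromosomal pairwise LD values up to
#' `max_pair_distance`, applies the sample-size correction to every r2,
#' and summarizes per half-open distance bin (pooled and per chromosome):
#' pair count, mean and SD of corrected r2 (raw alongside).  Also reports
#' the adjacent-pair mean r2 (consecutive post-QC markers, plus the
#' variant restricted to <= 10 kb), the fraction of <= 10 kb pairs with
#' r2 > 0.3, and the interpolated distance at which the binned mean
#' corrected r2 first drops through a threshold (linear interpolation
#' between bin midpoints).
#'
#' @param source a `haplotype_matrix` (direct counting) or
#'   `genotype_matrix` (two-locus EM).
#' @param bins bin edges in bp, see [ld_distance_bins()].
#' @param max_pair_distance largest pair distance considered (bp).
#' @param r2_threshold threshold for the crossing-distance statistic.
#' @return list of class `ld_decay` with elements `pairs`, `by_bin`,
#'   `by_chrom_bin`, `adjacent`, `threshold_crossing_bp`, `n_haplotypes`.
#' @export
ld_decay <- function(source, bins = ld_distance_bins(),
                     max_pair_distance = max(bins), r2_threshold = 0.2) {
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  tab <- ld_pair_table(source, max_pair_distance)
  if (nrow(tab)) {
    tab$r2_corrected <- correct_r2(tab$r2, tab$n_haplotypes)
    tab$bin <- cut(tab$distance_bp, bins, right = FALSE, include.lowest = FALSE)
  } else {
    tab$r2_corrected <- numeric(0)
    tab$bin <- factor(character(0), levels = levels(cut(numeric(0), bins, right = FALSE)))
  }
  lv <- levels(tab$bin)
  agg <- function(df) {
    data.frame(
      bin_lo_bp = bins[-length(bins)], bin_hi_bp = bins[-1],
      n_pairs = as.integer(table(df$bin)),
      mean_r2 = as.numeric(tapply(df$r2, df$bin, mean)),
      sd_r2 = as.numeric(tapply(df$r2, df$bin, sd)),
      mean_r2_corrected = as.numeric(tapply(df$r2_corrected, df$bin, mean)),
      sd_r2_corrected = as.numeric(tapply(df$r2_corrected, df$bin, sd)))
  }
  by_bin <- agg(tab)
  by_chrom <- do.call(rbind, lapply(split(tab, tab$chrom), function(df) {
    cbind(chrom = df$chrom[1], agg(df))
  }))
  adj <- tab[tab$adjacent, , drop = FALSE]
  adj10 <- adj[adj$distance_bp <= 1e4, , drop = FALSE]
  le10 <- tab[tab$distance_bp <= 1e4, , drop = FALSE]
  adjacent <- c(mean_r2_adjacent = mean(adj$r2_corrected),
                mean_r2_adjacent_10kb = mean(adj10$r2_corrected),
                frac_r2_gt_0.3_10kb = if (nrow(le10)) mean(le10$r2 > 0.3) else NaN,
                n_adjacent = nrow(adj))
  # threshold crossing: first downward pass of binned means at bin midpoints
  mid <- (by_bin$bin_lo_bp + by_bin$bin_hi_bp) / 2
  mu <- by_bin$mean_r2_corrected
  cross <- NA_real_
  ok <- which(!is.na(mu))
  if (length(ok) >= 2) {
    for (k in seq_len(length(ok) - 1)) {
      a <- ok[k]; b <- ok[k + 1]
      if (mu[a] >= r2_threshold && mu[b] < r2_threshold) {
        cross <- mid[a] + (mu[a] - r2_threshold) / (mu[a] - mu[b]) *
          (mid[b] - mid[a])
        break
      }
    }
  }
  structure(list(pairs = tab, by_bin = by_bin, by_chrom_bin = by_chrom,
                 adjacent = adjacent, threshold_crossing_bp = cross,
                 r2_threshold = r2_threshold,
                 n_haplotypes = if (nrow(tab)) tab$n_haplotypes[1] else NA),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay:", nrow(x$pairs), "pairs\n")
  cat(sprintf("  adjacent-pair mean corrected r2: %.4f (n = %d)\n",
              x$adjacent["mean_r2_adjacent"], as.integer(x$adjacent["n_adjacent"])))
  if (!is.na(x$threshold_crossing_bp))
    cat(sprintf("  mean r2 crosses %.2f at ~%.0f kb\n", x$r2_threshold,
                x$threshold_crossing_bp / 1000))
  print(x$by_bin[, c("bin_lo_bp", "bin_hi_bp", "n_pairs", "mean_r2_corrected")],
        row.names = FALSE)
  invisible(x)
}
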