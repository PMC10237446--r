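#' Signed-r table for short-range marker pairs
#'
#' All intra-chromosomal pairs within `max_distance`, with the signed
#' correlation r of the B-allele states.  Signs are meaningful across
#' populations only when both use the same allele orientation table
#' (alleleB = lexicographically larger observed allele, shared map).
#'
#' @param source `haplotype_matrix` or `genotype_matrix` (per [ld_decay()]).
#' @param max_distance largest pair distance in bp (default 100 kb).
#' @return data.frame `chrom, id_i, id_j, distance_bp, r_signed`.
#' @export
signed_r_table <- function(source, max_distance = 1e5) {
  tab <- ld_pair_table(source, max_distance)
  data.frame(chrom = tab$chrom,
             id_i = source$map$id[tab$i], id_j = source$map$id[tab$j],
             distance_bp = tab$distance_bp, r_signed = tab$r_signed,
             stringsAsFactors = FALSE)
}

#' Persistence of LD phase between two populations
#'
#' For marker pairs present (segregating) in both populations, the Pearson
#' correlation of signed r between populations, per half-open distance bin.
#' Bins with fewer than 2 shared pairs, or with zero variance in either
#' vector, get `NA`.
#'
#' @param tableA,tableB signed-r tables from [signed_r_table()], computed
#'   under a shared allele orientation.
#' @param bins bin edges in bp over the short range (default 10-kb bins over
#'   0-100 kb).
#' @return data.frame of class `phase_persistence`:
#'   `bin_lo_bp, bin_hi_bp, n_pairs, R`.
#' @export
phase_persistence <- function(tableA, tableB, bins = seq(0, 1e5, by = 1e4)) {
  key <- function(t) paste(t$id_i, t$id_j, sep = "\r")
  m <- match(key(tableA), key(tableB))
  use <- !is.na(m)
  rA <- tableA$r_signed[use]
  rB <- tableB$r_signed[m[use]]
  d <- tableA$distance_bp[use]
  bin <- cut(d, bins, right = FALSE, include.lowest = FALSE)
  lo <- bins[-length(bins)]; hi <- bins[-1]
  R <- n <- numeric(length(lo))
  for (k in seq_along(lo)) {
    sel <- which(as.integer(bin) == k)
    n[k] <- length(sel)
    R[k] <- if (n[k] >= 2 && sd(rA[sel]) > 0 && sd(rB[sel]) > 0)
      cor(rA[sel], rB[sel]) else NA_real_
  }
  structure(data.frame(bin_lo_bp = lo, bin_hi_bp = hi,
                       n_pairs = as.integer(n), R = R),
            class = c("phase_persistence", "data.frame"))
}
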