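#' One-sided 95% confidence bounds on |D'|
#'
#' Gabriel-style interval: the multinomial likelihood of the (possibly
#' fractional, EM-expected) haplotype counts is evaluated on a grid of
#' |D'| in \{0, 0.001, ..., 1\} with allele frequencies held at their
#' observed values; the bounds are the 5th and 95th percentiles of the
#' normalized likelihood mass over the grid.
#'
#' @param f a [two_locus_freqs()].
#' @param grid_step grid resolution on |D'|.
#' @return list `lower, upper` with `0 <= lower <= upper <= 1`.
#' @export
dprime_ci <- function(f, grid_step = 0.001) {
  pA <- f$fA; pB <- f$fB
  if (min(pA, 1 - pA, pB, 1 - pB) <= 0)
    return(list(lower = 0, upper = 1))        # degenerate: uninformative
  n <- f$n_haplotypes
  cnt <- n * c(f$fAB, f$fAb, f$faB, f$fab)
  D <- f$fAB * f$fab - f$fAb * f$faB
  # orient so that the observed D is non-negative (swap b <-> B)
  if (D < 0) {
    cnt <- cnt[c(2, 1, 4, 3)]
    pB <- 1 - pB
  }
  dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  dp <- seq(0, 1, by = grid_step)
  eps <- 1e-12
  hAB <- pmax(pA * pB + dp * dmax, eps)
  hAb <- pmax(pA * (1 - pB) - dp * dmax, eps)
  haB <- pmax((1 - pA) * pB - dp * dmax, eps)
  hab <- pmax((1 - pA) * (1 - pB) + dp * dmax, eps)
  ll <- cnt[1] * log(hAB) + cnt[2] * log(hAb) +
        cnt[3] * log(haB) + cnt[4] * log(hab)
  lik <- exp(ll - max(ll))
  cdf <- cumsum(lik) / sum(lik)
  list(lower = dp[which(cdf >= 0.05)[1]],
       upper = dp[which(cdf >= 0.95)[1]])
}

#' Classify a marker pair from its D' confidence bounds
#'
#' `"strong_ld"` if the upper bound reaches 0.98 and the lower bound 0.7;
#' `"strong_recombination"` if the upper bound is below 0.9; otherwise
#' `"uninformative"`.
#'
#' @param ci list with `lower`, `upper` (see [dprime_ci()]).
#' @param strong_upper,strong_lower,recomb_upper thresholds.
#' @return one of `"strong_ld"`, `"strong_recombination"`, `"uninformative"`.
#' @export
classify_pair <- function(ci, strong_upper = 0.98, strong_lower = 0.70,
                          recomb_upper = 0.90) {
  if (ci$upper >= strong_upper && ci$lower >= strong_lower) "strong_ld"
  else if (ci$upper < recomb_upper) "strong_recombination"
  else "uninformative"
}

# pair classification table for all intra-chromosomal pairs within span_bp
classify_pairs_table <- function(source, span_bp = 5e5) {
  phased <- inherits(source, "haplotype_matrix")
  map <- source$map
  out <- list()
  for (ch in unique(map$chrom)) {
    mi <- which(map$chrom == ch)
    if (length(mi) < 2) next
    pos <- map$pos_bp[mi]
    for (a in seq_len(length(mi) - 1)) {
      for (b in (a + 1):length(mi)) {
        if (pos[b] - pos[a] > span_bp) break
        f <- tryCatch(
          if (phased) haplotype_freqs_phased(source, mi[a], mi[b])
          else haplotype_freqs_em(source, mi[a], mi[b]),
          error = function(e) NULL)
        cls <- if (is.null(f)) "uninformative" else classify_pair(dprime_ci(f))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, i = mi[a], j = mi[b], class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), i = integer(), j = integer(),
                      class = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find haplotype blocks from pair classifications
#'
#' Gabriel-style: a candidate span is a run of consecutive markers whose
#' outermost pair is strong-LD and in which at least `min_strong_frac` of
#' the informative pairs (strong-LD + strong-recombination) are strong-LD.
#' Candidates are accepted greedily by decreasing physical length (ties:
#' leftmost start); accepted blocks may not overlap.  Spans are limited to
#' `span_bp`.
#'
#' @param pair_classes data.frame `chrom, i, j, class` as produced by
#'   `classify_pairs_table` (indices into `map`).
#' @param map the marker map.
#' @param min_strong_frac minimum strong-LD fraction among informative pairs.
#' @param span_bp maximum block span in bp.
#' @return data.frame of class `haplotype_blocks`:
#'   `chrom, first, last, start_bp, end_bp, n_snps, length_kb`.
#' @export
find_blocks <- function(pair_classes, map, min_strong_frac = 0.95,
                        span_bp = 5e5) {
  blocks <- list()
  for (ch in unique(pair_classes$chrom)) {
    pc <- pair_classes[pair_classes$chrom == ch, , drop = FALSE]
    mi <- sort(unique(c(pc$i, pc$j)))
    cls <- new.env(hash = TRUE)
    for (r in seq_len(nrow(pc)))
      assign(paste(pc$i[r], pc$j[r]), pc$class[r], envir = cls)
    getcls <- function(i, j) {
      v <- mget(paste(i, j), envir = cls, ifnotfound = list(NULL))[[1]]
      if (is.null(v)) NA_character_ else v
    }
    cand <- list()
    for (a in seq_along(mi)) {
      for (b in seq_along(mi)) {
        if (b <= a) next
        if (map$pos_bp[mi[b]] - map$pos_bp[mi[a]] > span_bp) break
        if (identical(getcls(mi[a], mi[b]), "strong_ld")) {
          sub <- pc[pc$i >= mi[a] & pc$j <= mi[b], , drop = FALSE]
          inf <- sub$class != "uninformative"
          if (sum(inf) >= 1 &&
              mean(sub$class[inf] == "strong_ld") >= min_strong_frac) {
            cand[[length(cand) + 1]] <- data.frame(
              chrom = ch, first = mi[a], last = mi[b],
              start_bp = map$pos_bp[mi[a]], end_bp = map$pos_bp[mi[b]])
          }
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand$len <- cand$end_bp - cand$start_bp
    cand <- cand[order(-cand$len, cand$start_bp), , drop = FALSE]
    taken <- rep(FALSE, nrow(map))
    for (r in seq_len(nrow(cand))) {
      span <- cand$first[r]:cand$last[r]
      if (any(taken[span])) next
      taken[span] <- TRUE
      nsnp <- sum(map$chrom == ch & map$pos_bp >= cand$start_bp[r] &
                    map$pos_bp <= cand$end_bp[r])
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = ch, first = cand$first[r], last = cand$last[r],
        start_bp = cand$start_bp[r], end_bp = cand$end_bp[r],
        n_snps = nsnp,
        length_kb = (cand$end_bp[r] - cand$start_bp[r]) / 1000)
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = integer(), first = integer(), last = integer(),
               start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), length_kb = numeric())
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("haplotype_blocks", "data.frame")
  res
}

#' Detect haplotype blocks on a dataset
#'
#' Convenience wrapper: classify all pairs within the search span, then
#' assemble non-overlapping blocks.
#'
#' @inheritParams find_blocks
#' @param source `haplotype_matrix` or `genotype_matrix`.
#' @return see [find_blocks()].
#' @export
detect_blocks <- function(source, min_strong_frac = 0.95, span_bp = 5e5) {
  find_blocks(classify_pairs_table(source, span_bp), source$map,
              min_strong_frac, span_bp)
}

#' Per-chromosome block summary
#'
#' Counts and coverage in the layout of a per-chromosome block table:
#' number of blocks, total block length (kb), percentage of the chromosome
#' span covered by blocks, and percentage of SNPs inside blocks.  The
#' chromosome length is the span from first to last mapped marker.
#'
#' @param blocks output of [find_blocks()].
#' @param map the marker map.
#' @return data.frame with one row per chromosome plus a `genome` total row.
#' @export
block_summary <- function(blocks, map) {
  chroms <- sort(unique(map$chrom))
  rows <- lapply(chroms, function(ch) {
    mpos <- map$pos_bp[map$chrom == ch]
    span <- if (length(mpos) > 1) max(mpos) - min(mpos) else 0
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    in_block <- if (nrow(b)) sum(vapply(seq_len(nrow(b)), function(r)
      sum(mpos >= b$start_bp[r] & mpos <= b$end_bp[r]), numeric(1))) else 0
    data.frame(chrom = as.character(ch), n_snps_total = length(mpos),
               span_bp = span, n_blocks = nrow(b),
               total_block_kb = sum(b$length_kb),
               snps_in_blocks = in_block,
               pct_length = if (span > 0) 100 * sum(b$length_kb) * 1000 / span else 0,
               pct_snps = if (length(mpos)) 100 * in_block / length(mpos) else 0,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  genome <- data.frame(chrom = "genome", n_snps_total = sum(per$n_snps_total),
                       span_bp = sum(per$span_bp),
                       n_blocks = sum(per$n_blocks),
                       total_block_kb = sum(per$total_block_kb),
                       snps_in_blocks = sum(per$snps_in_blocks),
                       pct_length = if (sum(per$span_bp) > 0)
                         100 * sum(per$total_block_kb) * 1000 / sum(per$span_bp) else 0,
                       pct_snps = if (sum(per$n_snps_total) > 0)
                         100 * sum(per$snps_in_blocks) / sum(per$n_snps_total) else 0,
                       stringsAsFactors = FALSE)
  out <- rbind(per, genome)
  out[, c("chrom", "n_blocks", "total_block_kb", "pct_length", "pct_snps",
          "n_snps_total", "snps_in_blocks", "span_bp")]
}
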