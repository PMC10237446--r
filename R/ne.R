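#' Expected r-squared under drift-recombination equilibrium
#'
#' Sved's relationship: `E[r2] = 1 / (4 c Ne + 1)` for recombination
#' distance c (Morgans) and effective size Ne.
#'
#' @param Ne effective population size (> 0).
#' @param c recombination distance in Morgans (> 0).
#' @return expected r-squared (vectorized).
#' @export
expected_r2 <- function(Ne, c) {
  if (any(Ne <= 0) || any(c <= 0)) stop("Ne and c must be positive")
  1 / (4 * c * Ne + 1)
}

#' Point estimate of Ne from mean r-squared at distance c
#'
#' Inversion of the Sved relationship with a mutation-correction constant:
#' `Ne = (1/r2 - alpha) / (4c)`; the associated generation is `t = 1/(2c)`.
#' `alpha = 1` is the no-mutation form; `alpha = 2.2` is the common
#' mutation-aware alternative.
#'
#' @param mean_r2 mean (sample-size-corrected) r-squared in (0, 1].
#' @param c recombination distance in Morgans.
#' @param alpha mutation-correction constant.
#' @return list `Ne, t_generations` (Ne may be negative for r2 above the
#'   drift ceiling; callers should drop such bins).
#' @export
ne_point <- function(mean_r2, c, alpha = 1) {
  if (any(mean_r2 <= 0)) stop("mean_r2 must be positive")
  if (any(c <= 0)) stop("c must be positive")
  list(Ne = (1 / mean_r2 - alpha) / (4 * c), t_generations = 1 / (2 * c))
}

#' Default genetic-distance bins for the Ne trajectory (cM)
#'
#' `<0.01, 0.01-0.02, 0.02-0.05, 0.05-0.1, 0.1-0.2, 0.2-0.5, 0.5-1, 1-2,
#' 2-5, 5-10, 10-20` cM.  With the 1 Mb = 1 cM map assumption these
#' convert to bp edges at `1 cM = 1e6 / 100 Morgan`.
#' @return numeric vector of bin edges in cM.
#' @export
ne_distance_bins_cm <- function() {
  c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20)
}

#' Ne trajectory from binned LD decay
#'
#' Computes the LD decay of `source` over the genetic-distance bins
#' (physical distance converted at `mb_per_cm` Mb = 1 cM), then per bin:
#' the mean sample-size-corrected r-squared, the representative distance
#' c (arithmetic midpoint, in Morgans; `"harmonic"` optional), the Ne
#' point estimate, and the generation `t = 1/(2c)`.  Bins with undefined
#' or non-positive Ne are dropped with a message.
#'
#' @param source `haplotype_matrix` or `genotype_matrix`, or a precomputed
#'   [ld_decay()] object whose bins correspond to `bins_cm`.
#' @param bins_cm genetic-distance bin edges in cM.
#' @param mb_per_cm map scale (Mb per cM), default 1.
#' @param alpha mutation-correction constant (see [ne_point()]).
#' @param c_rep `"midpoint"` or `"harmonic"` representative distance.
#' @param min_pairs bins with fewer pairs are dropped.
#' @param verbose report dropped bins?
#' @return data.frame of class `ne_trajectory`:
#'   `c_lo_cM, c_hi_cM, c_rep_M, t_generations, n_pairs, mean_r2_adj, Ne`.
#' @export
ne_trajectory <- function(source, bins_cm = ne_distance_bins_cm(),
                          mb_per_cm = 1, alpha = 1,
                          c_rep = c("midpoint", "harmonic"),
                          min_pairs = 2, verbose = FALSE) {
  c_rep <- match.arg(c_rep)
  bp_per_cm <- mb_per_cm * 1e6
  if (inherits(source, "ld_decay")) {
    decay <- source
    if (nrow(decay$by_bin) != length(bins_cm) - 1)
      stop("precomputed decay does not match the requested bins")
  } else {
    decay <- ld_decay(source, bins = bins_cm * bp_per_cm)
  }
  bb <- decay$by_bin
  lo_cm <- bins_cm[-length(bins_cm)]; hi_cm <- bins_cm[-1]
  crep_m <- switch(c_rep,
                   midpoint = (lo_cm + hi_cm) / 2 / 100,
                   harmonic = 2 / (1 / pmax(lo_cm, 1e-6) + 1 / hi_cm) / 100)
  Ne <- t_gen <- rep(NA_real_, length(lo_cm))
  ok <- !is.na(bb$mean_r2_corrected) & bb$n_pairs >= min_pairs &
    bb$mean_r2_corrected > 0
  est <- ne_point(pmax(bb$mean_r2_corrected[ok], 1e-12), crep_m[ok], alpha)
  Ne[ok] <- est$Ne; t_gen <- 1 / (2 * crep_m)
  res <- data.frame(c_lo_cM = lo_cm, c_hi_cM = hi_cm, c_rep_M = crep_m,
                    t_generations = t_gen, n_pairs = bb$n_pairs,
                    mean_r2_adj = bb$mean_r2_corrected, Ne = Ne)
  drop <- is.na(res$Ne) | res$Ne <= 0
  if (verbose && any(drop))
    message(sum(drop), " bin(s) dropped (empty or non-positive Ne estimate)")
  res <- res[!drop, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ne_trajectory", "data.frame")
  res
}
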