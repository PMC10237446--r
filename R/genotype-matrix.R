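#' @useDynLib ldpop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rbinom rexp rpois runif sd var setNames quantile
#' @importFrom utils read.table write.table
NULL

#' Missing-genotype code
#'
#' Genotype calls are stored as integer counts of the B allele (0, 1, 2);
#' missing calls are `NA_integer_`.
#' @keywords internal
GENO_MISSING <- NA_integer_

#' Construct a marker map
#'
#' A marker map is a data.frame with one row per SNP: marker id, chromosome
#' label (1-26 = ovine autosomes, 27 = X, 0 = unknown placement), 1-based
#' physical position, and the two alleles.  Allele B is by convention the
#' lexicographically larger of the two observed alleles, so that B-allele
#' counts (and hence the sign of r) are comparable across populations.
#'
#' @param id character vector of unique marker ids.
#' @param chrom integer chromosome labels (0 = unknown, 27 = X).
#' @param pos_bp 1-based physical positions.
#' @param alleleA,alleleB single-character alleles, `alleleA != alleleB`.
#' @return data.frame with columns `id, chrom, pos_bp, alleleA, alleleB`.
#' @export
marker_map <- function(id, chrom, pos_bp, alleleA = "A", alleleB = "B") {
  n <- length(id)
  m <- data.frame(id = as.character(id),
                  chrom = rep_len(as.integer(chrom), n),
                  pos_bp = as.numeric(pos_bp),
                  alleleA = rep_len(as.character(alleleA), n),
                  alleleB = rep_len(as.character(alleleB), n),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$id)) stop("duplicate marker id: ", m$id[anyDuplicated(m$id)])
  if (any(m$pos_bp < 1)) stop("marker positions must be >= 1")
  bad <- m$alleleA == m$alleleB
  if (any(bad)) stop("alleleA == alleleB at marker ", m$id[which(bad)[1]])
  m
}

#' Construct a genotype matrix
#'
#' The central container: an integer matrix of B-allele counts (0/1/2,
#' `NA` = missing) with samples in rows and markers in columns, plus a
#' marker map and per-sample population labels.
#'
#' @param calls integer matrix, samples x markers, values in \{0,1,2,NA\}.
#' @param map marker map (see [marker_map()]), one row per column of `calls`.
#' @param sample_id character vector of unique sample ids.
#' @param population character vector of population labels (recycled).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, sample_id = NULL, population = "pop1") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_id)) sample_id <- sprintf("s%d", seq_len(nrow(calls)))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " markers but map has ", nrow(map))
  if (length(sample_id) != nrow(calls)) stop("sample_id length mismatch")
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  rownames(calls) <- sample_id
  colnames(calls) <- map$id
  rownames(map) <- NULL
  g <- structure(list(calls = calls, map = map,
                      sample_id = sample_id,
                      population = rep_len(as.character(population), nrow(calls))),
                 class = "genotype_matrix")
  check_map_sorted(g$map)
  g
}

check_map_sorted <- function(map) {
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_markers(x), "markers\n")
  cat("  chromosomes:", paste(sort(unique(x$map$chrom)), collapse = " "), "\n")
  cat("  populations:", paste(names(table(x$population)), table(x$population),
                              sep = ":", collapse = " "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname genotype_matrix
#' @export
n_markers <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' Order-preserving selection of samples and/or markers; all container
#' invariants are re-checked on the result.
#'
#' @param g a `genotype_matrix`.
#' @param samples logical/integer/character selector of samples (default all).
#' @param markers logical/integer/character selector of markers (default all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  si <- resolve_index(samples, g$sample_id, "sample")
  mi <- resolve_index(markers, g$map$id, "marker")
  genotype_matrix(g$calls[si, mi, drop = FALSE],
                  g$map[mi, , drop = FALSE],
                  sample_id = g$sample_id[si],
                  population = g$population[si])
}

resolve_index <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    if (length(sel) != length(ids)) stop(what, " mask length mismatch")
    return(which(sel))
  }
  if (is.character(sel)) {
    i <- match(sel, ids)
    if (anyNA(i)) stop("unknown ", what, " id: ", sel[which(is.na(i))[1]])
    return(i)
  }
  as.integer(sel)
}

#' Construct a haplotype matrix
#'
#' Phased haplotypes: a binary matrix with 2 rows per sample (consecutive
#' rows belong to one sample) and one column per marker, sharing the marker
#' map of a genotype matrix.  Row pairs must sum to the sample's genotype
#' codes wherever the genotype is non-missing.
#'
#' @param haps integer matrix in \{0,1\}, `2 * n_samples` rows.
#' @param map marker map.
#' @param sample_id sample ids (one per row pair).
#' @param population population labels.
#' @param genotypes optional `genotype_matrix` to validate against.
#' @return object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haps, map, sample_id = NULL, population = "pop1",
                             genotypes = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) %% 2L != 0L) stop("haplotype rows must come in sample pairs")
  ns <- nrow(haps) %/% 2L
  if (!all(haps %in% c(0L, 1L))) stop("haplotype alleles must be 0 or 1")
  if (ncol(haps) != nrow(map)) stop("haplotype/marker dimension mismatch")
  if (is.null(sample_id)) sample_id <- sprintf("s%d", seq_len(ns))
  rownames(map) <- NULL
  h <- structure(list(haps = haps, map = map,
                      sample_id = as.character(sample_id),
                      population = rep_len(as.character(population), ns)),
                 class = "haplotype_matrix")
  if (!is.null(genotypes)) check_hap_consistency(h, genotypes)
  h
}

check_hap_consistency <- function(h, g) {
  if (!identical(h$map$id, g$map$id)) stop("marker maps differ")
  if (!identical(h$sample_id, g$sample_id)) stop("sample ids differ")
  gsum <- h$haps[seq(1L, nrow(h$haps), by = 2L), , drop = FALSE] +
          h$haps[seq(2L, nrow(h$haps), by = 2L), , drop = FALSE]
  ok <- is.na(g$calls) | gsum == g$calls
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("haplotypes inconsistent with genotypes at sample '",
         g$sample_id[idx[1]], "', marker '", g$map$id[idx[2]], "'")
  }
  invisible(TRUE)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$haps) / 2, "samples (",
      nrow(x$haps), "haplotypes ) x", ncol(x$haps), "markers\n")
  invisible(x)
}

#' Collapse phased haplotypes to genotypes
#' @param h a `haplotype_matrix`.
#' @return a `genotype_matrix` with the same map and samples.
#' @export
haplotypes_to_genotypes <- function(h) {
  gsum <- h$haps[seq(1L, nrow(h$haps), by = 2L), , drop = FALSE] +
          h$haps[seq(2L, nrow(h$haps), by = 2L), , drop = FALSE]
  genotype_matrix(gsum, h$map, sample_id = h$sample_id, population = h$population)
}

#' Subset a haplotype matrix by sample / marker
#' @inheritParams subset_genotypes
#' @param h a `haplotype_matrix`.
#' @export
subset_haplotypes <- function(h, samples = NULL, markers = NULL) {
  si <- resolve_index(samples, h$sample_id, "sample")
  mi <- resolve_index(markers, h$map$id, "marker")
  rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  haplotype_matrix(h$haps[rows, mi, drop = FALSE], h$map[mi, , drop = FALSE],
                   sample_id = h$sample_id[si], population = h$population[si])
}
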