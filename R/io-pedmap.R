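#' Read PLINK PED/MAP text files
#'
#' Parses the classic whitespace-delimited PED/MAP pair into a
#' [genotype_matrix()].  The MAP file supplies marker id, chromosome and
#' physical position; the PED file supplies six metadata columns (family id,
#' individual id, father, mother, sex, phenotype) followed by two allele
#' columns per marker.  "0" denotes a missing allele; a half-missing genotype
#' (one allele called) is set fully missing.  At each marker, allele B is the
#' lexicographically larger of the observed alleles, so B-allele counts are
#' orientation-stable across files sharing allele labels.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (4 columns: chrom, id, cM, bp).
#' @param population optional population label(s); defaults to the PED
#'   family-id column.
#' @return a `genotype_matrix`.
#' @export
read_ped_map <- function(ped_path, map_path, population = NULL) {
  map_raw <- tryCatch(
    read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric", "numeric")),
    error = function(e) {
      if (length(readLines(map_path)) == 0)       # empty MAP = zero markers
        data.frame(V1 = character(), V2 = character(),
                   V3 = numeric(), V4 = numeric())
      else stop("cannot parse MAP file: ", conditionMessage(e))
    })
  if (ncol(map_raw) != 4) stop("MAP file must have 4 columns")
  chrom <- suppressWarnings(as.integer(map_raw[[1]]))
  chrom[map_raw[[1]] %in% c("X", "x")] <- 27L
  chrom[is.na(chrom)] <- 0L
  nm <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  nsamp <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * nm
  alle <- matrix("0", nrow = nsamp, ncol = 2L * nm)
  fam <- iid <- character(nsamp)
  for (i in seq_len(nsamp)) {
    f <- fields[[i]]
    if (length(f) != expected)
      stop("PED line ", i, " has ", length(f), " fields, expected ", expected,
           " for ", nm, " markers")
    fam[i] <- f[1]; iid[i] <- f[2]
    if (nm > 0) alle[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(iid)) iid <- paste(fam, iid, sep = "_")

  calls <- matrix(NA_integer_, nrow = nsamp, ncol = nm)
  aA <- aB <- character(nm)
  for (j in seq_len(nm)) {
    a1 <- alle[, 2L * j - 1L]; a2 <- alle[, 2L * j]
    half <- xor(a1 == "0", a2 == "0")
    a1[half] <- "0"; a2[half] <- "0"          # half-calls dropped
    obs <- sort(unique(c(a1, a2)[c(a1, a2) != "0"]))
    if (length(obs) > 2)
      stop("marker ", map_raw[[2]][j], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0) obs <- c("A", "B")
    if (length(obs) == 1) obs <- c(obs, paste0(obs, "x"))  # monomorphic: synthetic B
    # alleleB = lexicographically larger observed allele
    aA[j] <- obs[1]; aB[j] <- obs[2]
    cnt <- (a1 == aB[j]) + (a2 == aB[j])
    cnt[a1 == "0"] <- NA_integer_
    calls[, j] <- as.integer(cnt)
  }
  # file order is preserved (round-trip identity); genotype_matrix enforces
  # strictly increasing positions within each chromosome
  map <- marker_map(map_raw[[2]], chrom, map_raw[[4]], aA, aB)
  genotype_matrix(calls, map, sample_id = iid,
                  population = if (is.null(population)) fam else population)
}

#' Write PLINK PED/MAP text files
#'
#' Inverse of [read_ped_map()]: `read_ped_map(write_ped_map(g))` reproduces
#' `g` exactly (codes, marker order, sample labels) whenever both alleles of
#' a marker are observed at least once - always true post-QC.  A marker
#' monomorphic for allele B cannot keep its orientation through the text
#' format (the PED records allele labels, not which one is B) and reads back
#' as monomorphic allele A.  Missing calls are written as "0 0".
#'
#' @param g a `genotype_matrix`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  map <- g$map
  if (nrow(map) > 0)
    write.table(data.frame(map$chrom, map$id, 0, map$pos_bp),
                map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  else writeLines(character(0), map_path)
  nm <- n_markers(g)
  ns <- n_samples(g)
  out <- file(ped_path, "w")
  on.exit(close(out))
  for (i in seq_len(ns)) {
    x <- g$calls[i, ]
    a1 <- ifelse(is.na(x), "0", ifelse(x >= 1L, map$alleleB, map$alleleA))
    a2 <- ifelse(is.na(x), "0", ifelse(x == 2L, map$alleleB, map$alleleA))
    pair <- character(2L * nm)
    if (nm > 0) { pair[seq(1, 2 * nm, 2)] <- a1; pair[seq(2, 2 * nm, 2)] <- a2 }
    writeLines(paste(c(g$population[i], g$sample_id[i], "0", "0", "0", "-9",
                       pair), collapse = " "), out)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a phased-haplotype table
#'
#' Whitespace-delimited table, one row per haplotype (two consecutive rows
#' per sample, in the sample order of `g`), one 0/1 column per marker of
#' `g`.  Consistency with the genotypes is enforced: each sample's two rows
#' must sum to its genotype code at every non-missing site.
#'
#' @param haps_path path to the table.
#' @param g the `genotype_matrix` the haplotypes belong to.
#' @return a `haplotype_matrix`.
#' @export
read_phased <- function(haps_path, g) {
  raw <- tryCatch(as.matrix(read.table(haps_path, header = FALSE)),
                  error = function(e) matrix(integer(), 0, n_markers(g)))
  if (nrow(raw) == 0)
    return(haplotype_matrix(matrix(integer(), 0, n_markers(g)), g$map,
                            sample_id = character(0), population = character(0)))
  if (ncol(raw) != n_markers(g))
    stop("phased table has ", ncol(raw), " columns, expected ", n_markers(g))
  if (nrow(raw) != 2L * n_samples(g))
    stop("phased table has ", nrow(raw), " rows, expected ", 2L * n_samples(g))
  haplotype_matrix(raw, g$map, sample_id = g$sample_id,
                   population = g$population, genotypes = g)
}
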