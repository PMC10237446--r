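#' Simulation configuration
#'
#' Conditions for the forward Wright-Fisher genotype simulator.  Defaults
#' emulate a medium-density ovine array population: 26 autosomes, target
#' post-filter marker spacing 58 kb, recombination 1 cM/Mb, output MAF
#' floor 0.05.  Burn-in defaults to `6 * Ne` generations so linkage
#' disequilibrium reaches drift-recombination equilibrium.  With no
#' mutation most initial loci drift to fixation during burn-in, so
#' candidate loci are planted `candidate_factor` times denser than the
#' target spacing; the survivors of burn-in plus the MAF filter land near
#' the target density (array-ascertainment emulation).
#'
#' @param Ne diploid effective population size.
#' @param n_generations burn-in generations (default `6 * Ne`).
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param marker_spacing_bp target mean output spacing between markers.
#' @param candidate_factor candidate-marker densification factor.
#' @param recomb_rate recombination rate in Morgans/bp (1e-8 = 1 cM/Mb).
#' @param mutation_rate per-locus per-gamete recurrent (allele-flip)
#'   mutation rate; 0 (default) disables mutation.  A small nonzero rate
#'   keeps variant turnover alive in long multi-Ne divergence studies,
#'   where drift alone degenerates the joint marker set.
#' @param sample_size diploid individuals sampled at the end (<= Ne).
#' @param min_maf_at_output markers below this MAF in the sample are dropped.
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(Ne = 100, n_generations = 6 * Ne, n_chromosomes = 26,
                       chrom_length_bp = 5e6, marker_spacing_bp = 58000,
                       candidate_factor = 20, recomb_rate = 1e-8,
                       mutation_rate = 0,
                       sample_size = min(50, Ne), min_maf_at_output = 0.05,
                       seed = 1) {
  if (any(c(Ne, n_generations, n_chromosomes, chrom_length_bp,
            marker_spacing_bp, candidate_factor, sample_size) <= 0))
    stop("simulation sizes must be positive")
  if (sample_size > Ne) stop("sample_size cannot exceed Ne")
  structure(list(Ne = as.integer(Ne), n_generations = as.integer(n_generations),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 marker_spacing_bp = marker_spacing_bp,
                 candidate_factor = candidate_factor,
                 recomb_rate = recomb_rate,
                 mutation_rate = mutation_rate,
                 sample_size = as.integer(sample_size),
                 min_maf_at_output = min_maf_at_output,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# candidate marker positions for one chromosome
candidate_positions <- function(cfg) {
  sp <- cfg$marker_spacing_bp / cfg$candidate_factor
  pos <- seq(sp, cfg$chrom_length_bp, by = sp)
  round(pos)
}

# evolve a whole-population haplotype pool; returns list of per-chromosome
# L x 2Ne matrices plus positions
evolve_pool <- function(cfg, generations, pool = NULL) {
  lapply(seq_len(cfg$n_chromosomes), function(ch) {
    if (is.null(pool)) {
      pos <- candidate_positions(cfg)
      L <- length(pos)
      p0 <- runif(L, 0.05, 0.95)
      H <- matrix(rbinom(L * 2 * cfg$Ne, 1L, rep(p0, times = 2 * cfg$Ne)),
                  nrow = L, ncol = 2 * cfg$Ne)
      storage.mode(H) <- "integer"
    } else {
      H <- pool[[ch]]$H
      pos <- pool[[ch]]$pos
    }
    pos_m <- pos * cfg$recomb_rate
    mu <- if (is.null(cfg$mutation_rate)) 0 else cfg$mutation_rate
    list(H = wf_evolve(H, pos_m, generations, mu), pos = pos)
  })
}

# draw a diploid sample from a pool and build matrices; markers failing the
# MAF floor (computed in the sample) are dropped
sample_pool <- function(cfg, pool, sample_idx = NULL, prefix = "s",
                        population = "pop1") {
  if (is.null(sample_idx))
    sample_idx <- sample(cfg$Ne, cfg$sample_size)
  hap_cols <- as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
  hap_list <- list(); map_list <- list()
  for (ch in seq_along(pool)) {
    H <- pool[[ch]]$H[, hap_cols, drop = FALSE]       # L x 2n
    p <- rowMeans(H)
    maf <- pmin(p, 1 - p)
    keep <- maf >= cfg$min_maf_at_output
    if (!any(keep)) next
    hap_list[[length(hap_list) + 1]] <- t(H[keep, , drop = FALSE])
    pos <- pool[[ch]]$pos[keep]
    map_list[[length(map_list) + 1]] <- data.frame(
      id = sprintf("snp_%d_%d", ch, pos), chrom = ch, pos_bp = pos,
      stringsAsFactors = FALSE)
  }
  if (!length(map_list)) stop("no markers survived the output MAF filter")
  mapd <- do.call(rbind, map_list)
  map <- marker_map(mapd$id, mapd$chrom, mapd$pos_bp, "A", "B")
  haps <- do.call(cbind, hap_list)
  ids <- paste0(prefix, seq_len(cfg$sample_size))
  h <- haplotype_matrix(haps, map, sample_id = ids, population = population)
  list(haplotypes = h, genotypes = haplotypes_to_genotypes(h))
}

#' Simulate a population forward in time
#'
#' Discrete-generation Wright-Fisher simulation of `2 Ne` haplotypes per
#' chromosome: initial haplotypes are drawn with per-locus allele
#' frequencies uniform on [0.05, 0.95]; each offspring haplotype is a
#' recombinant mosaic of a random parent's pair (Poisson crossovers at
#' `recomb_rate`); after `n_generations` of burn-in, `sample_size` diploids
#' are drawn without replacement and markers below the output MAF floor are
#' dropped.  Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param population population label for the sampled individuals.
#' @return list `haplotypes` (a `haplotype_matrix`), `genotypes`
#'   (the matching `genotype_matrix`).
#' @export
simulate_population <- function(cfg = sim_config(), population = "pop1") {
  set.seed(cfg$seed)
  pool <- evolve_pool(cfg, cfg$n_generations)
  sample_pool(cfg, pool, population = population)
}

#' Split one ancestral population into two diverged ones
#'
#' Evolves a single ancestral pool through burn-in, duplicates it, evolves
#' the two copies independently for `divergence_generations`, and samples
#' each.  The two outputs share the candidate marker placement and allele
#' orientation; the emitted marker set is the intersection of markers
#' passing the output MAF floor in both samples (segregating in both).
#'
#' @param cfg a [sim_config()].
#' @param divergence_generations generations since the split (0 = two
#'   samples of the same generation).
#' @return list of two elements `popA`, `popB`, each a list
#'   `haplotypes, genotypes`.
#' @export
split_populations <- function(cfg = sim_config(), divergence_generations = 0) {
  set.seed(cfg$seed)
  anc <- evolve_pool(cfg, cfg$n_generations)
  poolA <- evolve_pool(cfg, divergence_generations, pool = anc)
  poolB <- evolve_pool(cfg, divergence_generations, pool = anc)
  if (divergence_generations == 0 && 2 * cfg$sample_size <= cfg$Ne) {
    # same generation: draw disjoint individual sets so the two samples
    # share no animals
    perm <- sample(cfg$Ne, 2 * cfg$sample_size)
    ia <- perm[seq_len(cfg$sample_size)]
    ib <- perm[cfg$sample_size + seq_len(cfg$sample_size)]
  } else ia <- ib <- NULL
  a <- sample_pool(cfg, poolA, sample_idx = ia, prefix = "a", population = "popA")
  b <- sample_pool(cfg, poolB, sample_idx = ib, prefix = "b", population = "popB")
  shared <- intersect(a$haplotypes$map$id, b$haplotypes$map$id)
  a <- lapply(a, function(x)
    if (inherits(x, "haplotype_matrix")) subset_haplotypes(x, markers = shared)
    else subset_genotypes(x, markers = shared))
  b <- lapply(b, function(x)
    if (inherits(x, "haplotype_matrix")) subset_haplotypes(x, markers = shared)
    else subset_genotypes(x, markers = shared))
  list(popA = a, popB = b)
}

#' Inject autozygous tracts into a genotype matrix
#'
#' Ground-truth generator for F_ROH recovery: per sample, non-overlapping
#' intervals with exponential lengths (mean `tract_length_mb`) are placed
#' uniformly over the autosomes until the target coverage `phi` of the
#' total marker span is reached (the last tract is truncated, so realized
#' coverage equals the target up to interval-end rounding).  Within a
#' tract every heterozygous call becomes one of the two homozygotes with
#' probability 1/2 each - one haplotype overwriting the other.
#'
#' @param g a `genotype_matrix`.
#' @param phi target autozygous fraction in [0, 1).
#' @param tract_length_mb mean tract length (Mb).
#' @param seed integer seed.
#' @param max_tries placement attempts per tract before giving up.
#' @return list `genotypes` (modified copy), `truth` (data.frame
#'   `sample_id, chrom, start_bp, end_bp`), `phi` (per-sample realized
#'   coverage).
#' @export
inject_autozygosity <- function(g, phi, tract_length_mb = 5, seed = 1,
                                max_tries = 1e5) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  set.seed(seed)
  chroms <- unique(g$map$chrom)
  spans <- vapply(chroms, function(ch) {
    p <- g$map$pos_bp[g$map$chrom == ch]
    c(min(p), max(p))
  }, numeric(2))
  lens <- spans[2, ] - spans[1, ]
  L <- sum(lens)
  target <- phi * L
  calls <- g$calls
  truth <- list(); realized <- numeric(n_samples(g))
  for (s in seq_len(n_samples(g))) {
    placed <- data.frame(chrom = integer(), start = numeric(), end = numeric())
    cum <- 0; tries <- 0
    while (cum < target) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place tracts to coverage ", phi,
             " (mean length too large for the genome?)")
      len <- rexp(1, 1 / (tract_length_mb * 1e6))
      len <- min(len, target - cum + 1)           # truncate the last tract
      ch_i <- sample(length(chroms), 1, prob = lens)
      if (len >= lens[ch_i]) next
      start <- spans[1, ch_i] + runif(1) * (lens[ch_i] - len)
      end <- start + len
      same <- placed$chrom == ch_i
      if (any(same & placed$start < end & placed$end > start)) next
      placed <- rbind(placed,
                      data.frame(chrom = ch_i, start = start, end = end))
      cum <- cum + len
      mi <- which(g$map$chrom == chroms[ch_i] & g$map$pos_bp >= start &
                    g$map$pos_bp <= end)
      if (length(mi)) {
        het <- which(!is.na(calls[s, mi]) & calls[s, mi] == 1L)
        if (length(het))
          calls[s, mi[het]] <- 2L * rbinom(length(het), 1L, 0.5)
      }
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = g$sample_id[s], chrom = chroms[ch_i],
        start_bp = start, end_bp = end, stringsAsFactors = FALSE)
    }
    realized[s] <- cum / L
  }
  g2 <- genotype_matrix(calls, g$map, sample_id = g$sample_id,
                        population = g$population)
  list(genotypes = g2,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(sample_id = character(), chrom = integer(),
                    start_bp = numeric(), end_bp = numeric()),
       phi = realized)
}

#' Simulate unlinked genotypes under Hardy-Weinberg equilibrium
#'
#' Array-like null data with no LD and no autozygosity: per-marker B-allele
#' frequencies drawn uniform on `freq_range`, genotypes binomial(2, p).
#' Useful as a false-positive control for ROH detection and a calibration
#' target for the GRM-family inbreeding estimators.
#'
#' @param n_samples diploid individuals.
#' @param n_chromosomes autosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param spacing_bp inter-marker spacing.
#' @param freq_range range of B-allele frequencies.
#' @param seed integer seed.
#' @param population population label.
#' @return a `genotype_matrix`.
#' @export
simulate_hwe_genotypes <- function(n_samples = 50, n_chromosomes = 26,
                                   markers_per_chrom = 1640,
                                   spacing_bp = 58000,
                                   freq_range = c(0.05, 0.95), seed = 1,
                                   population = "pop1") {
  set.seed(seed)
  nm <- n_chromosomes * markers_per_chrom
  p <- runif(nm, freq_range[1], freq_range[2])
  calls <- matrix(rbinom(n_samples * nm, 2L, rep(p, each = n_samples)),
                  nrow = n_samples, ncol = nm)
  map <- marker_map(paste0("m", seq_len(nm)),
                    rep(seq_len(n_chromosomes), each = markers_per_chrom),
                    rep(seq_len(markers_per_chrom) * spacing_bp,
                        times = n_chromosomes))
  genotype_matrix(calls, map, population = population)
}

#' Plant QC violations into a clean genotype matrix
#'
#' Deterministic fixture builder for the QC cascade accounting: overwrites
#' selected clean markers/samples with low-MAF markers, low-call-rate
#' markers, an all-homozygote HWE violation (half 0, half 2), unplaced
#' markers (chromosome 0), X-linked markers (chromosome 27), and
#' high-missingness samples.  Markers are taken from the end of the map so
#' the remaining matrix stays clean; a truth record lists what was planted
#' where.
#'
#' @param g a clean `genotype_matrix` (should pass QC untouched).
#' @param n_low_maf,n_low_call,n_hwe,n_unplaced,n_x counts of planted
#'   marker violations.
#' @param n_bad_samples samples made > 10% missing.
#' @param seed integer seed.
#' @return list `genotypes`, `truth` (named list of planted ids).
#' @export
plant_qc_violations <- function(g, n_low_maf = 0, n_low_call = 0, n_hwe = 0,
                                n_unplaced = 0, n_x = 0, n_bad_samples = 0,
                                seed = 1) {
  set.seed(seed)
  need <- n_low_maf + n_low_call + n_hwe + n_unplaced + n_x
  if (need > n_markers(g)) stop("not enough markers to plant violations")
  if (n_bad_samples > n_samples(g)) stop("not enough samples")
  calls <- g$calls; map <- g$map
  ns <- n_samples(g)
  take <- n_markers(g) - seq_len(need) + 1L  # from the end of the map
  idx <- split(take, rep.int(c("low_maf", "low_call", "hwe", "unplaced", "x"),
                             c(n_low_maf, n_low_call, n_hwe, n_unplaced, n_x)))
  for (j in idx$low_maf) {                    # one B allele in one het
    calls[, j] <- 0L
    calls[sample(ns, 1), j] <- 1L
  }
  for (j in idx$low_call)                     # 10% missing (call rate 0.90)
    calls[sample(ns, max(1, ceiling(0.1 * ns))), j] <- NA_integer_
  for (j in idx$hwe) {                        # 50/0/50 split: no hets at p=0.5
    half <- ns %/% 2
    calls[, j] <- c(rep(0L, half), rep(2L, ns - half))
  }
  map$chrom[idx$unplaced] <- 0L
  map$chrom[idx$x] <- 27L
  for (s in seq_len(n_bad_samples)) {         # 30% missing genotypes
    nm <- n_markers(g)
    calls[s, sample(nm, ceiling(0.3 * nm))] <- NA_integer_
  }
  # chromosome relabelling may break position sortedness; rebuild map order
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]; rownames(map) <- NULL
  calls <- calls[, ord, drop = FALSE]
  g2 <- genotype_matrix(calls, map, sample_id = g$sample_id,
                        population = g$population)
  truth <- list(low_maf = g$map$id[idx$low_maf],
                low_call = g$map$id[idx$low_call],
                hwe = g$map$id[idx$hwe],
                unplaced = g$map$id[idx$unplaced],
                x_linked = g$map$id[idx$x],
                bad_samples = g$sample_id[seq_len(n_bad_samples)])
  list(genotypes = g2, truth = truth)
}
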