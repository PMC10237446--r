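#' Pipeline configuration
#'
#' Settings for the one-command analysis sequence.  Any component left
#' `NULL` uses the package default.
#'
#' @param out_dir output directory (created if absent).
#' @param qc a [qc_config()].
#' @param ld_bins LD-decay bin edges in bp.
#' @param phase_bins phase-persistence bin edges in bp.
#' @param roh a [roh_params()] (its `min_snp_count`, when `NULL`, is
#'   calibrated per population via [min_roh_snps()]).
#' @param ne_bins_cm Ne-trajectory bin edges in cM.
#' @param ne_alpha mutation-correction constant for Ne.
#' @param mb_per_cm map scale.
#' @param n_pca_axes PCA axes to emit.
#' @param seed seed recorded in the manifest (stages are deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, qc = qc_config(),
                            ld_bins = ld_distance_bins(),
                            phase_bins = seq(0, 1e5, by = 1e4),
                            roh = roh_params(),
                            ne_bins_cm = ne_distance_bins_cm(),
                            ne_alpha = 1, mb_per_cm = 1, n_pca_axes = 10,
                            seed = 1) {
  structure(list(out_dir = out_dir, qc = qc, ld_bins = ld_bins,
                 phase_bins = phase_bins, roh = roh,
                 ne_bins_cm = ne_bins_cm, ne_alpha = ne_alpha,
                 mb_per_cm = mb_per_cm, n_pca_axes = n_pca_axes, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Per population: QC cascade, diversity summary, PCA coordinates, LD
#' decay, haplotype blocks, ROH segments, inbreeding table (three
#' GRM-family estimators plus F_ROH), and Ne trajectory; per population
#' pair: a phase-persistence table.  Every stage writes a TSV under
#' `cfg$out_dir` so any stage can be re-examined in isolation; a manifest
#' records the configuration and package version.  A stage failure aborts
#' with the stage name; partial outputs are kept next to a `FAILED` marker.
#'
#' @param populations named list of `genotype_matrix` objects (one per
#'   population).  Populations must share marker ids / allele orientation
#'   for the phase-persistence stage to be meaningful.
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of class `pipeline_bundle`: per-population
#'   result objects plus the output paths.
#' @export
run_pipeline <- function(populations, cfg) {
  if (length(populations) < 1) stop("need at least one population")
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste(name, conditionMessage(e)), failed)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  bundle <- list(populations = list(), pairs = list(), out_dir = cfg$out_dir)
  tables <- list()
  for (nm in names(populations)) {
    pdir <- file.path(cfg$out_dir, nm)
    dir.create(pdir, showWarnings = FALSE)
    g0 <- populations[[nm]]
    qc <- stage(paste0(nm, ":qc"), run_qc(g0, cfg$qc))
    write_tsv(qc$report, file.path(pdir, "qc_report.tsv"))
    g <- qc$genotypes
    if (n_markers(g) == 0 || n_samples(g) == 0)
      stop("population '", nm, "': nothing left after QC")
    div <- stage(paste0(nm, ":diversity"), heterozygosity(g))
    write_tsv(div$per_snp, file.path(pdir, "diversity_per_snp.tsv"))
    write_tsv(data.frame(stat = names(div$means), value = div$means),
              file.path(pdir, "diversity_summary.tsv"))
    pca <- stage(paste0(nm, ":pca"), tryCatch(
      pca_genotypes(g, cfg$n_pca_axes), error = function(e) NULL))
    if (!is.null(pca))
      write_tsv(data.frame(sample_id = pca$sample_id,
                           population = pca$population, pca$scores),
                file.path(pdir, "pca_coordinates.tsv"))
    decay <- stage(paste0(nm, ":ld"), ld_decay(g, cfg$ld_bins))
    write_tsv(decay$by_bin, file.path(pdir, "ld_decay.tsv"))
    blocks <- stage(paste0(nm, ":blocks"), detect_blocks(g))
    write_tsv(blocks, file.path(pdir, "blocks.tsv"))
    write_tsv(block_summary(blocks, g$map),
              file.path(pdir, "block_summary.tsv"))
    rp <- cfg$roh
    if (rp$min_snp_count <= 1L) {
      mh <- div$means[["mean_Ho"]]
      if (is.finite(mh) && mh > 0 && mh < 1)
        rp$min_snp_count <- min_roh_snps(n_markers(g), n_samples(g),
                                         mean_het = mh)
    }
    segs <- stage(paste0(nm, ":roh"), detect_roh(g, rp))
    write_tsv(segs, file.path(pdir, "roh_segments.tsv"))
    spans <- tapply(g$map$pos_bp, g$map$chrom, function(p) max(p) - min(p))
    fr <- f_roh(segs, g$sample_id, sum(spans),
                chrom_lengths_bp = as.list(spans))
    inb <- stage(paste0(nm, ":inbreeding"), grm_inbreeding(g))
    inb$F_ROH <- fr$F_ROH[match(inb$sample_id, fr$sample_id)]
    write_tsv(inb, file.path(pdir, "inbreeding.tsv"))
    write_tsv(roh_length_classes(segs, g$sample_id, g$population),
              file.path(pdir, "roh_length_classes.tsv"))
    traj <- stage(paste0(nm, ":ne"),
                  ne_trajectory(g, cfg$ne_bins_cm, cfg$mb_per_cm, cfg$ne_alpha))
    write_tsv(traj, file.path(pdir, "ne_trajectory.tsv"))
    bundle$populations[[nm]] <- list(qc = qc, diversity = div, pca = pca,
                                     ld = decay, blocks = blocks, roh = segs,
                                     inbreeding = inb, ne = traj,
                                     genotypes = g)
  }
  nms <- names(populations)
  if (length(nms) >= 2) {
    for (a in seq_len(length(nms) - 1)) {
      for (b in (a + 1):length(nms)) {
        key <- paste(nms[a], nms[b], sep = "_vs_")
        ga <- bundle$populations[[nms[a]]]$genotypes
        gb <- bundle$populations[[nms[b]]]$genotypes
        pp <- stage(paste0(key, ":phase"), {
          ta <- signed_r_table(ga, max(cfg$phase_bins))
          tb <- signed_r_table(gb, max(cfg$phase_bins))
          phase_persistence(ta, tb, cfg$phase_bins)
        })
        write_tsv(pp, file.path(cfg$out_dir, paste0("phase_", key, ".tsv")))
        bundle$pairs[[key]] <- pp
      }
    }
  } else message("single population: phase-persistence stage skipped")
  manifest <- c(paste0("ldpop_version\t", as.character(utils::packageVersion("ldpop"))),
                paste0("seed\t", cfg$seed),
                paste0("populations\t", paste(nms, collapse = ",")),
                paste0("qc\t", paste(names(unclass(cfg$qc)),
                                     vapply(unclass(cfg$qc), function(x)
                                       paste(format(x), collapse = "|"), ""),
                                     sep = "=", collapse = ";")))
  writeLines(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

#' Digest of a pipeline bundle
#'
#' Headline numbers per population: post-QC dimensions, mean adjacent-pair
#' corrected r2, fraction of <= 10 kb pairs with r2 > 0.3, number of
#' haplotype blocks, mean F_ROH, and the Ne estimate at the most recent
#' generation available.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()], or the path of
#'   a bundle directory.
#' @return data.frame digest (one row per population), printed on request.
#' @export
summarize_run <- function(bundle) {
  if (is.character(bundle)) return(summarize_run_dir(bundle))
  rows <- lapply(names(bundle$populations), function(nm) {
    p <- bundle$populations[[nm]]
    ne_recent <- if (nrow(p$ne)) p$ne$Ne[which.min(p$ne$t_generations)] else NA
    data.frame(population = nm,
               n_samples = n_samples(p$genotypes),
               n_snps = n_markers(p$genotypes),
               mean_adjacent_r2 = unname(p$ld$adjacent["mean_r2_adjacent"]),
               frac_r2_gt_0.3_10kb = unname(p$ld$adjacent["frac_r2_gt_0.3_10kb"]),
               n_blocks = nrow(p$blocks),
               mean_F_ROH = mean(p$inbreeding$F_ROH, na.rm = TRUE),
               Ne_recent = ne_recent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

summarize_run_dir <- function(dir) {
  pops <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  if (!length(pops)) stop("no population outputs found under ", dir)
  rows <- lapply(pops, function(nm) {
    rd <- function(f) {
      p <- file.path(dir, nm, f)
      if (file.exists(p)) read.table(p, header = TRUE, sep = "\t") else NULL
    }
    qc <- rd("qc_report.tsv"); inb <- rd("inbreeding.tsv")
    blk <- rd("blocks.tsv"); ne <- rd("ne_trajectory.tsv")
    data.frame(population = nm,
               n_samples = if (!is.null(qc)) qc$remaining[7] else NA,
               n_snps = if (!is.null(qc)) qc$remaining[8] else NA,
               n_blocks = if (!is.null(blk)) nrow(blk) else NA,
               mean_F_ROH = if (!is.null(inb)) mean(inb$F_ROH, na.rm = TRUE) else NA,
               Ne_recent = if (!is.null(ne) && nrow(ne))
                 ne$Ne[which.min(ne$t_generations)] else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
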