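# ldpop

Population-genomic analysis of diploid SNP-array genotypes, built for the
kind of study that characterizes livestock breeds from a single chip:
quality control, genetic diversity, population structure, linkage
disequilibrium (LD) and its decay, persistence of LD phase between
populations, haplotype blocks, runs of homozygosity (ROH), genomic
inbreeding, and LD-based historical effective population size (Ne).  It is
aimed at animal-breeding and conservation geneticists who need the whole
sequence as one reproducible, tested pipeline rather than a chain of
external binaries, plus a ground-truth simulator to validate every stage.

## Methods at the core

With haplotype frequencies f_AB, f_Ab, f_aB, f_ab and allele frequencies
f_A, f_a, f_B, f_b at a marker pair:

* **LD**: D = f_AB f_ab − f_Ab f_aB;  r = D / √(f_A f_a f_B f_b);
  r² = r²;  D′ = |D| / D_max.  Every reported r² carries the sample-size
  correction r²_adj = (r² − 1/n) / (1 − 1/n), n = haplotypes.  Unphased
  genotypes go through the standard two-locus EM; phased input is counted
  directly.
* **Phase persistence**: R_kk′ = Pearson correlation, across shared marker
  pairs in a distance bin, of signed r between populations k and k′ — the
  statistic that decides whether populations can share a genomic-selection
  training set.
* **Haplotype blocks**: Gabriel-style confidence bounds on D′
  (strong LD: upper ≥ 0.98 and lower ≥ 0.7), ≥95% informative pairs in
  strong LD, greedy longest-first non-overlapping assembly.
* **ROH / inbreeding**: PLINK-style sliding-window scan (20-SNP windows,
  ≤1 het, density and gap limits) with the false-positive-calibrated
  minimum run length l = ⌈ln(α/(n_s·n_i)) / ln(1 − het)⌉;
  F_ROH = Σ L_ROH / L_AUTO; plus the GRM-family estimators Fhat1 (GRM
  diagonal), Fhat2 (excess homozygosity), Fhat3 (uniting-gamete
  correlation).
* **Effective population size**: Sved's E[r²] ≈ 1/(4cNe + 1) inverted per
  genetic-distance bin, Ne = (1/r²_adj − α)/(4c), dated t = 1/(2c)
  generations ago, with 1 Mb = 1 cM by default.
* **Simulator**: forward Wright–Fisher with recombination (Rcpp core,
  R-RNG reproducible), array-like marker ascertainment, autozygosity
  injection with known coverage, population splits, planted QC violations.

The methods vignette (`vignettes/ldpop-methods.Rmd`) derives each stage,
its defaults, and the design decisions.

## Worked example

Simulate an equilibrium population at Ne = 100 (twenty 5-Mb chromosomes,
1 cM/Mb, 100 animals sampled), run it through QC, diversity, LD and the Ne
trajectory:

```r
library(ldpop)
cfg <- sim_config(Ne = 100, n_chromosomes = 20, chrom_length_bp = 5e6,
                  sample_size = 100, seed = 1)
sim <- simulate_population(cfg)
qc  <- run_qc(sim$genotypes, qc_config(n_tests_for_bonferroni = 50000))
print(qc)
#> QC cascade ( 100 animals x 2204 SNPs in )
#>   animals_low_call_rate    removed 0
#>   snps_low_maf             removed 0
#>   snps_low_call_rate       removed 0
#>   snps_hwe_deviation       removed 0
#>   snps_unknown_position    removed 0
#>   snps_sex_chromosome      removed 0
#>   remaining: 100 animals x 2204 SNPs (HWE threshold 1e-06)
heterozygosity(qc$genotypes)
#> diversity: Ho 0.3933 +- 0.1161 | He 0.3881 +- 0.1113 | MAF 0.2981 | spacing 23.7 kb
```

The clean simulated data passes every filter (the threshold 1e-06 is
0.05/50,000, the Bonferroni-corrected HWE level for a 50k array), and
observed heterozygosity matches its Hardy–Weinberg expectation.  LD and the
Ne trajectory from the phased haplotypes:

```r
dec <- ld_decay(sim$haplotypes)
dec$adjacent["mean_r2_adjacent"]      # 0.970  (adjacent pairs, ~24 kb apart)
ne_trajectory(sim$haplotypes, bins_cm = c(0.5, 1, 2, 5))
#>   c_lo_cM c_hi_cM c_rep_M t_generations n_pairs mean_r2_adj  Ne
#> 1     0.5       1  0.0075          66.7   27192      0.2483 101
#> 2     1.0       2  0.0150          33.3   28231      0.0968 156
#> 3     2.0       5  0.0350          14.3   32980      0.0612 110
```

Each row dates an Ne estimate t = 1/(2c) generations back: at this genome
size a single run scatters by tens of percent around the simulated Ne = 100
(bin estimates 101/156/110 here); averaging 15 replicate simulations, as
the acceptance script does, recovers it within a few percent.  The same
objects feed `detect_blocks()`, `detect_roh()`/`f_roh()`,
`grm_inbreeding()` and, for two populations, `phase_persistence()`;
`run_pipeline()` chains everything and writes one TSV per stage.

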