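---
title: "Population-genomic LD, inbreeding and Ne estimation with ldpop: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic LD, inbreeding and Ne estimation with ldpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldpop)
```

ldpop reimplements, as one tested toolkit, the analysis sequence used in
SNP-array studies of livestock population structure: genotype quality
control, diversity summaries, principal component analysis, pairwise linkage
disequilibrium (LD) and its decay with distance, persistence of LD phase
between populations, haplotype-block detection, runs of homozygosity (ROH)
with four genomic inbreeding estimators, and LD-based historical effective
population size (Ne).  This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the bundled simulator does
and does not emulate, and the numerical choices a maintainer would want
written down.

## Data model

Genotypes are stored as a `genotype_matrix`: an integer matrix of B-allele
counts (0/1/2, `NA` missing) with a marker map (id, chromosome 1--26 for the
ovine autosomes, 27 = X, 0 = unplaced; 1-based bp position; the two allele
labels).  **Allele B is always the lexicographically larger of the two
observed alleles.**  This one rule fixes the sign of the LD correlation r
everywhere: signed r is only comparable across populations when both use the
same orientation, which matters for phase persistence.  Orientation has no
effect on r-squared, D' or any other reported statistic.

Half-missing PED genotypes (one allele called) are set fully missing -- the
strict convention.  Intervals are reported inclusive of both endpoint SNP
positions.  Phased haplotypes, when available, are a `haplotype_matrix`
(two rows per sample) validated against the genotypes: the two rows must sum
to the genotype code at every non-missing site.  PED/MAP text round-trips
exactly whenever both alleles of a marker are observed (always true after
QC); the text format cannot carry the orientation of a marker monomorphic
for allele B.

## Quality control

`run_qc()` applies six sequential filters, each counted on the survivors of
the previous step so the report rows plus the remainder add up to the input:

1. animals with more than 10% missing genotypes;
2. SNPs with minor allele frequency below 0.05;
3. SNPs with call rate below 95%;
4. SNPs deviating from Hardy--Weinberg equilibrium at the Bonferroni-corrected
   per-test level (0.05 experiment-wise over the pre-QC SNP count; with a
   50,000-SNP array this is the conventional 1e-6), tested within each
   population, exact test;
5. SNPs of unknown genomic position;
6. SNPs on sex chromosomes.

MAF-before-call-rate is deliberate: it mirrors the accounting order of the
QC tables this package is meant to reproduce.  Marker statistics are
recomputed once after the sample-removal step, so step-2--4 decisions use
the retained animals only.  The HWE test is the standard conditional exact
construction (probability of the heterozygote count given the allele
counts; two-sided p sums outcomes no more probable than the observed one),
computed with log-factorials; a chi-square alternative was considered and
rejected because the exact test is what array-QC tools use at these sample
sizes.  `run_qc()` is idempotent: a second pass removes nothing.

PCA standardizes each marker by its mean 2p and SD sqrt(2p(1-p)),
mean-imputes missing calls (zero after centring), and takes the singular
value decomposition; variance fractions come from the squared singular
values.  Mean imputation is the standard convention when the missing
fraction is small post-QC; it shrinks affected samples slightly toward the
origin.

## Pairwise LD

For two biallelic loci with haplotype frequencies fAB, fAb, faB, fab:

* D = fAB fab - fAb faB;
* signed r = D / sqrt(fA fa fB fb), and r2 = r^2;
* D' = |D| / Dmax, where Dmax = min(fA fb, fa fB) if D > 0 and
  min(fA fB, fa fb) if D < 0 (D = 0 gives D' = 0).

Signed r equals the Pearson correlation of the two binary haplotype columns;
the test suite checks this exhaustively for every two-locus table with up to
12 haplotypes.

Every reported r2 receives the finite-sample correction
`r2_adj = (r2 - 1/n) / (1 - 1/n)` with n the number of haplotypes: a pair of
unlinked loci has E[r2] of about 1/n, and the correction zeroes that chance
level while leaving r2 = 1 fixed.  Negative corrected values are retained,
not clipped, so bin means stay unbiased.  D' is computed from the raw
frequencies; the correction is defined only for r2.

**Phased vs unphased input.**  With phased haplotypes, frequencies come from
direct counting.  With genotypes only, the two-locus EM estimator resolves
the double-heterozygote phase ambiguity: all other genotype combinations
determine their haplotypes, and the E-step splits double heterozygotes
between coupling and repulsion in the ratio implied by the current frequency
estimates.  Initialization is at linkage equilibrium (deterministic),
convergence tolerance 1e-10 on the largest frequency change, 1000-iteration
cap (exceeding it is an error, not a silent result).  EM is the standard
genotype-based r2 estimator; external statistical phasers are out of scope.
At 200 diploids the EM and phased estimates of r2 agree to ~0.01 on
average; a single strong-LD pair can differ by ~0.03 because the realized
phase of double heterozygotes is one binomial draw while EM uses its
expectation -- an irreducible information gap, not an estimator defect.

**LD decay.**  All intra-chromosomal pairs up to 20 Mb are binned by
physical distance into half-open [lo, hi) bins (defaults 0--0.01 up to
10--20 Mb); a pair exactly on an edge goes to the upper bin.  Reported per
bin: pair count, mean and SD of corrected (and raw) r2.  Alongside: the
adjacent-pair mean r2 (consecutive post-QC markers), the same restricted to
pairs within 10 kb (both variants are emitted because "adjacent SNPs at
distances up to 10 kb" is ambiguous between the two readings), the fraction
of <=10 kb pairs with r2 > 0.3, and the distance at which the binned mean
first crosses a threshold (default 0.2), linearly interpolated between bin
midpoints.  Pairs with either marker missing in more than half the samples
are skipped.

## Persistence of LD phase

For two populations genotyped on the same oriented marker set,
`phase_persistence()` correlates the signed r of shared marker pairs within
short-range distance bins (default 10-kb bins over 0--100 kb; the sub-100-kb
resolution matches how such results are plotted).  Only pairs segregating in
both populations enter.  The statistic per bin is the ordinary Pearson
correlation with the bin's own means and SDs; bins with fewer than two
shared pairs or zero variance are reported as undefined rather than
extrapolated.  High persistence at a distance means marker effects phased in
one population transfer to the other at that marker density -- the criterion
for pooling populations into one genomic-selection training set.

## Haplotype blocks

Block detection follows the confidence-bound definition: for each marker
pair within a 500-kb search span, a one-sided 95% interval on |D'| is
computed by evaluating the multinomial likelihood of the (EM-expected)
haplotype counts on a grid of D' in {0, 0.001, ..., 1} with allele
frequencies fixed at their observed values; the bounds are the 5th and 95th
percentiles of the normalized likelihood mass.  The 0.001 grid matches the
reference implementation's accuracy at negligible cost.  Pairs are
classified as strong LD (upper bound >= 0.98 and lower >= 0.7), strong
recombination (upper < 0.9), or uninformative.  A candidate block is a run
of consecutive markers whose outermost pair is strong LD and in which at
least 95% of informative pairs are strong LD (minimum one informative pair,
so two-marker blocks are allowed).  Candidates are accepted greedily by
decreasing physical length, ties broken leftmost, no overlaps.  Only the
strong-LD thresholds are fixed by the definition; the recombination bound,
informative fraction and search span are the reference defaults and all
exposed as arguments.  Strictness at the printed boundaries (>= vs >) is a
configuration choice with no observable consequence at grid resolution.

Block summaries report, per chromosome and genome-wide, the block count,
total block length, percent of the chromosome span (first to last mapped
marker) covered, and percent of SNPs inside blocks.

## Runs of homozygosity and inbreeding

`detect_roh()` is a sliding-window scanner in the PLINK tradition with the
window parameters used for medium-density arrays: 20-SNP windows, at most 1
heterozygous and 5 missing calls per hit window, SNP hit-rate threshold
0.05, minimum run length 10 kb, density at least 1 SNP per 1000 kb, maximum
gap 1000 kb.  Eligible-SNP runs are trimmed to homozygous non-missing end
calls and split at oversized gaps.  When a run holds more heterozygotes than
the budget (possible when homozygous flanks extend a run past one stray het
on each side), it is shrunk to its longest sub-run within the budget rather
than discarded: discarding would delete genuine long autozygous tracts on
account of their flanks, and every reported segment still satisfies the
het limit.

The minimum SNP count per run is calibrated against chance:
`l = ceiling( ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het) )`,
the smallest run length expected to occur by chance fewer than alpha = 0.05
times in the whole dataset.  `mean_het` defaults to the post-QC mean
observed heterozygosity.  The pipeline applies the window flags as given
and reserves the conventional >= 1 Mb floor for the reporting stage
(`f_roh()`, length classes), reconciling the "10 kb flag" and "above 1 Mb"
conventions explicitly and configurably.

`F_ROH` is the summed length of segments (>= 1 Mb by default) over the
total autosome length; a per-chromosome variant uses each chromosome's
span.  Length classes ([1,5), [5,10), [10,15), [15,20), >=20 Mb) report the
mean per-individual count and total length per population; both the 15 and
20 Mb boundaries appear because both conventions are in circulation.

The three GRM-family estimators, computed per individual over usable loci
with within-population allele frequencies:

* `Fhat1` (GRM diagonal - 1): mean of (x - 2p)^2 / (2p(1-p)) minus 1;
* `Fhat2` (excess homozygosity): 1 - sum x(2-x) / sum 2p(1-p);
* `Fhat3` (uniting-gamete correlation): mean of
  (x^2 - (1+2p)x + 2p^2) / (2p(1-p)).

All three are unbounded below (negative values mean fewer homozygotes than
HWE expects); `Fhat2` is bounded above by 1, attained by an all-homozygous
individual.  When frequencies are estimated from the sample itself, the
population means of `Fhat1` and `Fhat3` coincide algebraically (their
per-locus difference is proportional to x - 2p, which averages to zero over
the individuals that defined p) -- a useful internal consistency check.
Since frequency-based estimators cannot separate identity-by-descent from
identity-by-state, `F_ROH` is the preferred inbreeding measure and the
other three are reported alongside.

## Effective population size

Under drift--recombination equilibrium the expected r2 at recombination
distance c (Morgans) is approximately `1 / (4 c Ne + 1)` (Sved's relation).
`ne_point()` inverts it: `Ne = (1/r2_adj - alpha) / (4c)`, with `alpha = 1`
by default (the no-mutation form; 2.2 is available for mutation-aware
analyses), and dates the estimate at `t = 1/(2c)` generations ago.
`ne_trajectory()` computes the LD decay over genetic-distance bins (<0.01 up
to 10--20 cM; physical distance converted at 1 Mb = 1 cM by default, map
scale configurable), takes the bin's mean corrected r2 and its midpoint c
(harmonic-mean option available), and emits (t, Ne) per bin, dropping
undefined or non-positive estimates with a notice.  Larger distances map to
more recent generations.

Known behaviour of this estimator family, visible in the validation
studies: bins below ~0.5 cM underestimate Ne somewhat (r2 saturates and
marker ascertainment inflates it) and bins in the 1--2 cM range can
overestimate it (the Sved form sits above the true E[r2] at moderate 4Nc);
at the study scale used in the tests (Ne = 100, twenty 5-Mb chromosomes,
100 sampled diploids, 15 replicates) the per-bin means across replicates in
the 0.5--5 cM range are within about 10% of the simulated value, and
single-replicate estimates scatter roughly +-50% -- Ne from LD needs genome-
and replicate-averaging.

## The synthetic-data generator

`simulate_population()` is a discrete-generation Wright--Fisher forward
simulation of 2Ne haplotypes per chromosome: each offspring haplotype is a
recombinant mosaic of one random parent's pair, with crossover counts
Poisson in map length (default 1 cM/Mb) and breakpoints uniform on the map.
The inner loop is compiled (Rcpp) and draws from R's RNG, so every result
is reproducible from `set.seed()`/`cfg$seed`.  Defaults emulate a
medium-density ovine array study: 26 autosomes, target output spacing 58 kb,
output MAF floor 0.05, burn-in 6 Ne generations -- long enough for LD at all
relevant distances to reach drift--recombination equilibrium.

Two design points deserve emphasis:

* **Ascertainment via candidate oversampling.**  With no mutation, a 6 Ne
  burn-in lets heterozygosity decay by e^-3, fixing ~95% of loci.  The
  generator therefore plants candidate loci `candidate_factor` (default 20,
  the reciprocal of the expected survival at the MAF floor) times denser
  than the target spacing; the segregating survivors land near the target
  density with a realistic U-flattened frequency spectrum, mimicking array
  ascertainment plus QC.
* **Optional recurrent mutation** (`mutation_rate`, default 0).  Pure drift
  is the right null for most checks, but it degenerates long split-population
  studies: after several Ne generations of divergence the only markers still
  segregating in both daughters sit in two-haplotype regions, where phase
  persistence is forced to 1 by conditioning.  A small flip rate
  (4 Ne mu of order 0.01--0.02) keeps variant turnover alive and restores the
  expected monotone decay of persistence with divergence time.

Degenerate regimes to avoid when configuring fixtures: a chromosome of c
Morgans holds only about 1 + 4 Ne c quasi-independent drift segments, so
very short chromosomes at small Ne (for example 2 Mb at Ne = 30) often lose
every marker during burn-in; fixtures here use chromosomes of at least 5 Mb.

What the generator does **not** emulate: genotyping error and missingness
mechanisms (QC fixtures plant those separately via
`plant_qc_violations()`), real ovine recombination-map heterogeneity,
selection, non-equilibrium demography beyond the provided splits and
bottleneck constructions, and the array's actual ascertainment scheme.
Passing tests therefore validate the estimators' statistical behaviour
under the stated models, not the biology of any particular breed.

`inject_autozygosity()` supplies ground truth for F_ROH: per sample it
places non-overlapping exponential-length tracts (mean 5 Mb) uniformly over
the autosomes until a target coverage phi is reached (the last tract is
truncated so the realized coverage equals the target), then forces every
genotype inside a tract homozygous, heterozygotes resolving to either
homozygote with probability 1/2.  Recovery of phi by
`detect_roh()` + `f_roh()` is verified to within +-0.02 at
phi = 0.05/0.10/0.25 by the test suite, with a null (no injection, >=42k
SNPs, HWE) mean F_ROH below 0.01 -- consistent with the alpha = 0.05
false-positive design of the minimum-SNP rule.

## Pipeline and outputs

`run_pipeline()` runs QC, diversity, PCA, LD decay, blocks, ROH,
inbreeding and the Ne trajectory per population, plus one phase-persistence
table per population pair, writing one TSV per stage (stable column order,
header row) plus a manifest; any stage failure aborts with the stage name
and leaves a `FAILED` marker next to the partial outputs.  Stage outputs
are files rather than in-memory handoffs so any stage can be re-examined in
isolation.  `summarize_run()` digests a bundle (object or directory) into
one row of headline numbers per population.  A thin command-line wrapper
over these functions ships in `inst/cli/ldpop.R`; the exported functions
are the primary interface.

## Validation problem sizes

The test suite and the acceptance script size their simulation studies as
follows, chosen to make Monte-Carlo error comfortably smaller than each
check's tolerance: Ne recovery at Ne = 100 with twenty 5-Mb chromosomes,
100 sampled diploids and 15 replicate simulations; F_ROH recovery on 50
samples x 42,640 markers (26 chromosomes at 58-kb spacing); estimator
calibration on 200 samples x 5,000 markers; phase-persistence divergence at
Ne = 100 with six 5-Mb chromosomes, a 30-kb map and three replicates per
divergence level; and the exhaustive oracles (two-locus tables to 12
haplotypes, HWE tables to 30 individuals) with no sampling at all.

## Known limitations

* The unphased LD path runs one EM per marker pair; for dense maps over
  long ranges the phased path (direct counting, vectorized) is much faster.
  Array-scale LD-decay scans on genotypes are practical within a chromosome
  but not genome-wide at 50k markers x 20 Mb range.
* D' confidence bounds hold allele frequencies fixed at their estimates (the
  reference behaviour); for very small samples the interval understates
  frequency uncertainty, which the uninformative class absorbs in practice.
* Ne estimates inherit the biases of the Sved inversion discussed above;
  they are trend instruments, not point measurements.
* The simulator's burn-in cost grows with Ne (6 Ne generations); very large
  Ne studies would want a coalescent generator instead, which is outside
  this package's dependency budget by design.
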