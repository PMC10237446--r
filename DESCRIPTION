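Package: ldpop
Title: Linkage Disequilibrium, Diversity and Genomic Inbreeding from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for SNP-array population genomics in livestock:
    quality control with a sequential filter cascade and exact Hardy-Weinberg
    testing, allele-frequency and heterozygosity summaries, genotype PCA,
    pairwise linkage disequilibrium (signed r, r-squared with sample-size
    correction, D') and LD-decay profiles over physical distance bins,
    persistence of LD phase between populations, Gabriel-style haplotype block
    detection from D' confidence bounds, PLINK-style runs-of-homozygosity
    detection with F_ROH and the three GRM-family genomic inbreeding
    estimators, and LD-based historical effective population size via the
    Sved relationship.  Includes a forward Wright-Fisher genotype simulator
    with tunable effective size, autozygosity injection and population splits
    for validation and ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
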