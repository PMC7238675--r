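Package: divscan
Title: Windowed Diversity, Divergence and Pedigree Scans for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic scans for diploid resequencing data:
    nucleotide diversity, segregating sites, Tajima's D, Weir-Cockerham F_ST
    (ratio-of-sums over windows) and the reduction-of-diversity (ROD)
    coefficient, with empirical-quantile outlier calling and a label-permutation
    estimate of the false-discovery rate. Companion tools cover the
    single-genotype low-heterozygosity (autozygosity) scan, haplotype-block
    inheritance tracing through pedigrees, genetic-map based scaffold anchoring
    with AGP output and Marey-map recombination rates, and a synthetic-data
    generator (Balding-Nichols two-population genotypes with planted sweeps,
    pedigree gene dropping, anchoring fixtures) that provides ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
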