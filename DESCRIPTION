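Package: divscan
Title: Windowed Divergence Scans, Selective-Sweep Detection and Distance
    Phylogenies for Two-Species Resequencing Data
Version: 0.1.0
Authors@R: person("divscan", "maintainers", email = "divscan@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic divergence analysis of a pair of
    closely related species from multi-sample VCF data: variant filtering and
    genotype-matrix construction, per-window nucleotide diversity, segregating
    sites, Tajima's D, Weir-Cockerham FST, absolute divergence (Dxy) and
    fixation-site counts, top-quantile outlier-window classification into
    adaptive and divergent selection candidates, a SweepFinder-style composite
    likelihood ratio scan for selective sweeps, and distance-based (NJ, UPGMA)
    phylogenies with Newick output. A bundled two-population divergence
    simulator (split, bottlenecks, migration, F1 hybrids, optional sweeps,
    haploid chloroplast) provides calibrated synthetic data for testing the
    whole pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    VariantAnnotation,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
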