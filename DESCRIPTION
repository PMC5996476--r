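Package: popgenscan
Title: Windowed Population-Genomic Scans for Domestication Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genetic statistics and selection scans for
    resequencing cohorts of wild and cultivated accessions. Computes
    nucleotide diversity (theta-pi), Watterson's theta and Tajima's D in
    sliding windows, Hudson F_ST and the reduction-of-diversity (ROD)
    statistic between wild and cultivated groups, and calls selective-sweep
    and balancing-selection regions by joint genome-wide percentile criteria.
    Also provides windowed identity-by-descent profiling with group-level
    AverIBD summaries and donor-group chromosome painting of admixed
    accessions, EM-based linkage-disequilibrium decay from unphased
    genotypes with Hardy-Weinberg exact-test site filtering, bootstrap
    neighbor-joining phylogenies from genotype p-distances, a d/(2T)
    evolution-rate estimator, and a permutation test for colocalization of
    sweep regions with QTL intervals. A hierarchical drift simulator
    generates synthetic multi-population cohorts with planted sweeps, IBD
    segments, admixture mosaics and a balanced locus, together with a
    machine-readable truth set, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    GenomeInfoDb,
    ape,
    phangorn,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Sequencing, Software
RoxygenNote: 7.3.3
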