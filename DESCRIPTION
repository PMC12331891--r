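Package: scrambleseq
Title: Simulation and Long-Read Genotyping of Cre/loxPsym Rearrangement
    Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying inducible Cre/loxPsym ("SCRaMbLE")
    rearrangement of loxPsym-segmented synthetic genome modules in yeast.
    Provides a signed-permutation genotype algebra for deletion, inversion
    and duplication events between loxPsym sites; exact enumeration of the
    deletion/inversion design space with a breadth-first reachability
    oracle; stochastic simulation of induced cell pools with reporter
    (GFP) gating, fitness-weighted selection and iterative rounds;
    nanopore-like amplicon read synthesis; a pool-level long-read genotype
    caller with copy-number summary statistics; and per-genotype
    structural-event annotation with gene-impact reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
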