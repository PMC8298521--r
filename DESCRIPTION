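Package: bulkmapr
Title: Bulked-Segregant Mapping and Linkage Refinement for Haploid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-genetic mapping-by-sequencing toolkit for haploid
    organisms such as moss protonemata. Simulates a haploid two-parent cross
    with a causal mutation (no-interference crossover model, configurable
    penetrance), selects a phenotypic bulk and simulates pooled sequencing
    allele depths; computes the per-SNP parental allele-depth fraction with
    sliding-window smoothing and peak detection to localise the causal
    locus; refines the interval by two-point linkage (Haldane map function)
    in individually genotyped segregants; and classifies and filters
    candidate variants to nonsynonymous and nonsense (stop-gained) changes
    within genes in the mapped interval. Includes restriction-fragment
    utilities for probe design checks and circular statistics for bending
    angle phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
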