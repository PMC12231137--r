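Package: soiltraits
Title: Community-Weighted Genomic Traits and Social Niche Breadth for Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links soil properties (pH, organic matter) to microbial genomic
    traits from amplicon data. Assigns genome size, rRNA operon copy number and
    GC content to amplicon sequence variants by iterative taxonomic-rank
    fallback against a trait reference, computes abundance-weighted per-sample
    trait means, estimates per-taxon social niche breadth from co-occurrence,
    runs isometric log-ratio phylofactorization and phylogenetic-signal
    statistics (Blomberg's K, Pagel's lambda, PGLS), and fits penalized
    additive trait-environment models. Includes a synthetic community
    generator with known ground truth (pH-structured Gaussian niches on a
    Yule phylogeny) so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    vegan,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
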