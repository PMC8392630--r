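Package: twindhmr
Title: Three-Phase Discovery of Differentially Hydroxymethylated Regions in
    Discordant Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for calling differentially hydroxymethylated
    regions (DhMRs) from 5hmC enrichment sequencing of case/control co-twins.
    Fragments are binned into fixed-width genomic windows, filtered with
    sample-specific Poisson cutoffs and a per-count-level false discovery
    rate rule, and joined into candidate regions. Region-level inference
    uses negative-binomial generalized linear models with analysis of
    deviance under three covariate models (none; leukocyte composition;
    leukocyte composition plus age) with a pair factor for the matched
    design, Benjamini-Hochberg adjustment, and directional-consistency
    selection. A three-phase design (discovery in training monozygotic
    pairs, validation in held-out monozygotic pairs, generalization to
    dizygotic pairs) is orchestrated end to end, including a portable PCA
    transformation, a single-node tanh linear classifier with restart
    selection, boundary geometry decomposition, and gene-model annotation
    summaries. A synthetic twin-cohort generator with known spiked effects
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
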