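Package: nodpool
Title: Strain Deconvolution and Selection Analysis for Pooled Nodule Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Select-and-resequence analysis of rhizobial strain communities in
    legume root nodules. Estimates per-sample strain frequencies from pooled
    sequencing reads scored against a reference panel of strain haplotypes
    (finite-mixture maximum likelihood via EM), derives nodule-community
    measures (log2 fold-change strain fitness, the exponent of Shannon
    diversity, and a frequency-weighted predicted host benefit), partitions
    fitness variance across experimental factors with permutation-tested
    redundancy analysis, and tests whether pairwise strain rankings persist in
    more complex communities. A synthetic-data generator simulates the full
    experimental design (inoculum construction, host selection into finite
    nodule pools, pooled sequencing) so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'em.R'
    'metrics.R'
    'nodpool-package.R'
    'observations-io.R'
    'panel-io.R'
    'pipeline.R'
    'ranks.R'
    'rda.R'
    'simulate.R'
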