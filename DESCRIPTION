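Package: breakprox
Title: Gene Expression Change Near Evolutionary Rearrangement Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide testing of whether genes that change expression
    between two species lie closer to evolutionary rearrangement breakpoint
    regions (BPRs) than the rest of the gene complement. Provides readers for
    BPR tables, gene annotations and differential-expression lists; selection
    of breakpoints on the evolutionary branches separating a species pair from
    an edge-labelled phylogeny; nearest-BPR distances and flanking-interval
    geometry for every gene; a truncated-exponential log-distance null model
    with exact density, CDF, mixture prediction and seeded sampler; two-sample
    Kolmogorov-Smirnov and Monte-Carlo position-resampling tests; a synthetic
    genome generator with a controllable planted proximity effect; and an
    end-to-end pipeline with log-scale histogram figures and closest-gene
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
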