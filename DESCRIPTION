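Package: quadarray
Title: Processing and Subset-Specific Classification of One-Color
    Microarrays with On-Chip Replicate Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-level processing of one-color expression microarrays on
    which every non-control probe is printed several times (on-chip
    quadruplicates). Implements global linear scaling of processed signals to
    a reference 75th percentile, four-rule exclusion of unreliable replicate
    features (manual flags, software outlier flags, interquartile-range
    fences, pixel-intensity coefficient of variation), geometric-mean
    collapse of surviving replicates, and substitution of a lower-intensity
    surrogate floor. On the collapsed expression matrix it classifies each
    probe, for every pair of cell subsets, as negligible, shared, or
    subset-specific using an expression floor and a fold-change threshold,
    and aggregates the calls into Venn summaries across independent
    experiments. A sample-size- and normality-gated two-group testing tree
    (exact Mann-Whitney U or unpaired t-test) is provided for accompanying
    cytometry-style group data, together with a seeded synthetic-array
    generator with planted ground truth and an end-to-end pipeline with a
    run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
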