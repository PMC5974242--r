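Package: spliceScore
Title: Alternative Splicing Detection from Exon and Junction Microarray Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects alternatively spliced exons from probe-level exon and
    junction microarray intensities. Each gene (transcript cluster) is fitted
    with a mixed model that decomposes probe-level variability into probe,
    array and exon-by-array components; the intra-cluster correlation of each
    exon ("exon score") ranks candidates, and predicted exon-by-array random
    effects ("array scores") are tested between biological groups with
    Benjamini-Hochberg correction. Annotated exon-exon junctions are then used
    to corroborate each candidate: a rank-based interaction test checks
    whether linking junctions track the median profile of their anchor probe
    sets, detection-above-background calls assess exclusion junctions, and
    each candidate is placed in one of four junction-support categories.
    Supported candidates can be labelled with an alternative-splicing event
    type from isoform composition. A synthetic-data generator with planted
    ground truth makes the whole pipeline testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
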