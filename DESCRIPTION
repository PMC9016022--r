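Package: iddakit
Title: Immune Deficiency and Dysregulation Activity (IDDA2.1) Scoring and Cohort Phenotype Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the IDDA2.1 clinical activity score for inborn errors of
    immunity with immune dysregulation from per-visit parameter tables: 14
    graded organ/feature items, capped hospitalization and intensive-care
    terms, supportive-care items, and a Karnofsky/Lansky performance-scale
    multiplier. Tracks scores longitudinally across therapy phases,
    aggregates cohorts into 17-axis feature-presence frequency profiles
    rendered as fixed-order radar ("kaleidoscope") charts, and clusters
    disease-by-feature frequency matrices (truncated logit transform,
    complete-linkage hierarchical clustering on Euclidean distances) into
    annotated heatmaps. Includes a seedable synthetic cohort generator with
    disease-archetype structure for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    grid,
    tools,
    pheatmap,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
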