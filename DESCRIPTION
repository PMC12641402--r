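Package: dysconn
Title: Normative Dysconnectivity Indices for Longitudinal Resting-State
    Functional Connectivity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-region deviation of resting-state functional
    connectivity from a healthy reference norm (dysconnectivity counts, DCC,
    and hemisphere-normalised dysconnectivity indices, DCI), tracks
    longitudinal change under an intervention with linear mixed models and
    Tukey post hoc effect sizes, relates regional change to clinical outcome
    changes by region-wise regression, and relates the spatial pattern of
    change to parcel-level gene expression via variogram-matched spatial
    surrogate maps, Spearman map-gene correlations and pre-ranked cell-type
    gene-set enrichment. Ships a synthetic-data generator with planted
    ground-truth effects so the whole pipeline is testable end to end
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    signal,
    jsonlite,
    fgsea
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
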