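Package: rankagree
Title: Rank-Invariant Agreement Analysis for Paired Ordinal Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reliability analysis for paired ordinal rating data using the
    rank-invariant (Svensson) approach: percentage agreement with point
    tolerance, the systematic disagreement measures relative position (RP)
    and relative concentration (RC), the random disagreement measure
    relative rank variance (RV) from augmented mean ranks, subject-level
    percentile bootstrap confidence intervals with confidence-interval-based
    classification of disagreements, ROC-style cumulative marginal curves,
    and floor/ceiling detection for sum scores.  Ships the 17-item
    Fugl-Meyer Assessment of the Lower Extremity (FMA-LE) as a built-in
    instrument, tools to enumerate intra- and inter-rater comparisons in
    multi-rater two-occasion study designs, a synthetic study generator
    with known systematic shift and rater noise for method validation, and
    an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
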