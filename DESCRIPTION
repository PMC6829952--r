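Package: germclock
Title: Stage-Wise Pathway Activity Profiling of Seed Germination Time-Course Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for profiling transcriptional pathway activity across the
    stages of seed germination from an FPKM expression matrix. Implements a
    nonparametric NOISeq-like differential-expression caller (fold change and
    signal-vs-noise probability thresholds), directional hypergeometric
    over-representation of Mapman functional categories with signed Z-values,
    the relative Z-value pathway-activity statistic (sigma-Z = Z_up - Z_down)
    under fixed-reference and continuous (adjacent-stage) contrast systems,
    quadrant concordance analysis between the two systems, stage-specific
    gene identification, and derivation of an ordered pathway-activation
    timetable. Includes a synthetic-data generator that plants a known
    category activation schedule so the whole pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
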