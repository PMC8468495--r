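Package: synfair
Title: Fairness Auditing for Paired Real and Synthetic Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Audits whether synthetic tabular health data represent
    protected subgroups as faithfully as the real data they were generated
    from. Implements the log disparity metric on subgroup representation
    rates together with its statistical-significance machinery
    (two-proportion z-test, Fisher exact fallback, Benjamini-Hochberg
    false-discovery-rate adjustment), a time-series log disparity metric
    built on Pearson-correlation and directional-symmetry resemblance of
    per-subgroup aggregated series, enumeration of the full subgroup
    lattice over categorical protected attributes, bias-injection
    simulators for end-to-end validation by parameter recovery, and
    exporters for flat result tables and hierarchical sunburst data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
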