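Package: inbdx
Title: Incremental Net Benefit of Single and Combined Diagnostic Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic tools for choosing and ordering binary
    diagnostic tests by their incremental net benefit (INB). Computes the
    value of diagnostic information, test and test-treatment thresholds in
    both the pre-test probability of disease and the cost-benefit trade-off
    of treatment, composite operating points and sequence-dependent expected
    testing losses for conjunctive (AND), disjunctive (OR) and majority
    protocols, argmax-INB protocol selection with decision-region maps over
    the probability/trade-off unit square, and ROC-frontier (efficiency)
    analysis. Ships worked case studies for prostate cancer, colorectal
    cancer and stable coronary artery disease screening, and a command-line
    interface over YAML test-panel configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
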