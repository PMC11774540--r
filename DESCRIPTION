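Package: groupitize
Title: Simulation and Analysis of Groupitizing in Numerosity Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-task studies of "groupitizing", the gain in
    numerosity-estimation precision when items are spatially clustered into
    subitizable subgroups. Generates grouped and ungrouped square-array
    stimuli on a calibrated visual-angle grid, simulates observers with
    scalar response variability under single- and dual-task attentional
    load, and runs the full precision pipeline: 3-SD outlier filtering,
    per-cell response statistics, Weber fractions, dual-task attentional
    cost, and the grouped-minus-ungrouped delta attentional cost. Includes
    the accompanying inferential machinery: repeated-measures ANOVA with
    Mauchly's test and Greenhouse-Geisser correction, Bonferroni-corrected
    paired t tests with Cohen's d, default (JZS) log10 Bayes factors,
    BIC-based inclusion Bayes factors, principal component analysis with
    oblimin rotation, and a-priori power computations for paired designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
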