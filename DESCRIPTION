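Package: bepilot
Title: Pilot Bioequivalence Analysis with the Cmax f2 Similarity Factor
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for planning and analysing two-treatment, two-sequence,
    two-period (2x2x2) crossover bioequivalence studies of highly variable
    drugs such as pazopanib. Simulates single-dose studies from a
    one-compartment oral-absorption pharmacokinetic model, derives
    non-compartmental metrics (Cmax, tmax, AUC truncated at 72 h, lambda_z,
    terminal half-life), runs the average-bioequivalence ANOVA on
    ln-transformed metrics (geometric least-square means, 90% confidence
    interval, intra-subject coefficient of variation), computes the
    Cmax-based f2 similarity factor on normalised mean concentration-time
    profiles together with its decision bands for proceeding to a pivotal
    study, and performs exact power and sample-size calculations for the
    two one-sided tests (TOST) procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
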