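Package: wgacorrect
Title: Correction of Differential Genotype Misclassification in
    Case-Control Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Corrects case-control genotype association analyses for
    differential misclassification, such as allelic drop-out in
    whole-genome-amplified buccal DNA. Misclassification probabilities are
    estimated from a gold-standard validation sample as a 3x3 discordance
    table; control genotypes are then stochastically reassigned over many
    imputation draws, an unconditional logistic regression model is fitted
    to each draw, and the draws are pooled with Rubin's rules to give
    corrected odds ratios, confidence intervals and Wald tests. Includes a
    synthetic-data suite that rebuilds the hypothetical case-control
    datasets and error patterns used to validate the method, plus
    command-line tools for discordance summaries, corrected analyses and
    the simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
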