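Package: methbridge
Title: Blood-Brain Concordance of DNA Methylation Lifestyle Predictor Scores
Version: 0.1.0
Authors@R:
    person("Methbridge", "Developers", email = "methbridge@example.org",
           role = c("aut", "cre"))
Description: Projects blood-derived DNA methylation (DNAm) predictor weights
    for lifestyle traits (smoking, HDL cholesterol, BMI, alcohol) onto
    normalized Illumina 450K/EPIC beta matrices from blood and post-mortem
    brain regions, and quantifies blood-brain and score-trait concordance.
    Includes probe- and sample-level quality-control filters (detection
    p-value, beadcount, call rate, methylation-predicted sex), platform
    harmonization by probe intersection, lifestyle phenotype derivation
    (pack years), Pearson/Spearman correlation inference with Fisher-z
    confidence intervals, a correlation power simulator, and a synthetic
    paired blood/brain cohort generator with known ground truth for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
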