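Package: spiderfear
Title: Simulated Behavioral, Psychometric, and fMRI Measures of Spider Fear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse a two-group (arachnophobic versus
    low-fear control) study combining questionnaire scores (SPQ, SNAQ, DS-R),
    a behavioral approach test, picture fear ratings, and block-design fMRI.
    Generates seeded synthetic cohorts with latent spider-fear, snake-fear and
    disgust-propensity traits; builds carryover-balanced block designs and
    HRF-convolved design matrices; simulates 4-D BOLD series with a planted
    spider-responsive region; fits voxelwise GLMs and contrast t-maps; derives
    a data-driven region of interest under family-wise error control and
    computes the Spider Fear Index (mean first-level t-statistic in the ROI,
    taken from an independent session); and runs the downstream multivariate
    analyses: redundancy analysis with sequential permutation tests, AIC-based
    linear-model reduction, linear discriminant classification, and Spearman
    rank correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    RNifti,
    jsonlite
Config/testthat/edition: 3
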