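Package: gastromot
Title: Organ-Bath Analysis of Human Gastric Myogenic Contractions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of isometric force recordings from
    gastric smooth-muscle organ-bath experiments. Detects spontaneous
    phasic (myogenic) contractions and computes the eight standard
    motility parameters (amplitude, total duration, time to peak, decay
    time, development/decay areas and rates) together with windowed
    muscle-tone and frequency summaries. Builds cumulative
    concentration-response curves, fits the Hill equation (pEC50, Emax,
    slope), locates threshold concentrations, and quantifies competitive
    antagonism by Schild regression (pKB) and the Gaddum-Schild equation
    (pA2). Includes paired/unpaired comparisons, one-way ANOVA with
    Dunnett's post hoc test, a combined-versus-sum super-additivity
    (synergy) test, Bland-Altman agreement analysis, and a synthetic
    force-trace generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
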