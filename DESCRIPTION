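Package: tandemdose
Title: Dosimetry-Guided Design and Efficacy Analysis for Tandem Alpha/Beta
    Radioligand Therapy Studies
Version: 0.1.0
Authors@R:
    person("Preclinical", "Dosimetry Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing preclinical tandem-isotope
    radioligand therapy experiments. Models nuclear decay data and branched
    decay-chain (Bateman) kinetics for Lu-177 and the Ac-225 series, derives
    equilibrium dose constants from bundled emission tables, converts ex vivo
    gamma-counting biodistribution measurements into percent-injected-activity
    uptake tables with Welch group comparisons, fits sum-of-exponential tumor
    time-activity curves with AICc model selection, computes cumulated activity
    and tumor self-dose per injected activity, matches injected activities
    across isotopes for equal absorbed dose and builds tandem prescriptions,
    and analyses longitudinal bioluminescence tumor burden and survival
    (Kaplan-Meier, log-rank, per-week ANOVA with Bonferroni contrasts). A
    seeded synthetic-cohort generator emulates the full experimental design so
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
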