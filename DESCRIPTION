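Package: protomort
Title: Plasma Proteomic Prognosis of Mortality in Stable COPD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for prognostic screening of plasma proteomic
    panels against long-term survival in stable chronic obstructive pulmonary
    disease. Provides missingness-aware differential-abundance screening with
    separate quantitative (t / Mann-Whitney on log2 abundances) and qualitative
    presence/absence (Barnard unconditional exact test) branches, functional
    annotation of candidate markers, aggregated conformal random-forest
    prediction of four-year mortality and days of survival, and coverage-aware
    performance summaries re-expressed at arbitrary disease prevalence. A
    synthetic two-platform cohort generator with planted effects and
    left-censored missingness makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
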