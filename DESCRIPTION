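Package: citsciBias
Title: Trait-Linked Representation Bias Between Unstructured and
    Semi-Structured Citizen Science Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies over- and under-representation of species in an
    unstructured citizen-science dataset (photo-based occurrence records)
    relative to a semi-structured one (effort-annotated checklists).
    Provides checklist quality filtering, per-state species prevalence
    trimming, a per-state log-log regression residual representation
    statistic, construction of detectability-related species traits (log
    body mass, plumage color index from RGB patches, mean flock size,
    ordinal IUCN status), and linear mixed models of the residuals on
    traits with a random intercept per state. Includes a synthetic-data
    generator with planted state and trait effects so the entire pipeline
    is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
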