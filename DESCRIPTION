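Package: pollenstoich
Title: Multi-Element Stoichiometry of Pollen and Trophic Stoichiometric
    Mismatch for Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-element stoichiometry of
    pollen-bearing flowers sampled under ambient and elevated CO2, and for
    the resulting nutritional mismatch between pollen and bee consumers.
    Provides validated long-format containers for elemental concentrations
    with hierarchical sampling lineage, unit normalisation and C:X ratio
    computation; the trophic stoichiometric ratio (TSR) nutrient-limitation
    index with assimilation-efficiency adjustment and quartile summaries;
    whole-composition comparisons via Bray-Curtis dissimilarity, PERMANOVA,
    non-metric multidimensional scaling and environmental fitting;
    per-response linear mixed models with nested random intercepts,
    Box-Cox transform selection and marginal/conditional R2; a hierarchical
    synthetic-data generator emulating the study design; and a
    configuration-driven pipeline that writes all report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
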