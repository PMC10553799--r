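Package: deprindex
Title: Construction and Agreement Analysis of Area-Level Deprivation Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds two widely used area-level socioeconomic deprivation
    indices from raw census-style indicator tables: a factor-weighted Area
    Deprivation Index (ADI) at the block-group level with standardization,
    national percentile ranking and population-weighted aggregation to
    census tracts, and the four-theme Social Vulnerability Index (SVI) at
    the tract level from directional item percentile rankings. Quantifies
    agreement between the two indices via Spearman correlation, a 10x10
    decile cross-tabulation and good/poor agreement classes, isolates the
    extreme-decile mismatch groups, and identifies the indicator items
    driving disagreement with Welch t-tests and Cohen's d effect sizes.
    Includes a synthetic census-microgeography generator with a latent
    deprivation factor and a tunable urban housing-cost confound for
    end-to-end validation, plus CSV/JSON/GeoJSON input-output and a
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
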