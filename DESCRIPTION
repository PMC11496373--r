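Package: climurf
Title: Population-Specific Climate-Sensitive Top-Height Curves from
    Universal Response Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Universal Response Functions (URFs) relating provenance-trial
    top height to provenance and site climate, and merges the selected URF into
    growth-and-yield top-height equations to obtain population-specific,
    climate-sensitive height-age curves. Includes tools to prepare
    provenance-trial tree measurements (health filtering, block-adjusted
    population means, common-age conversion), to manage annual climate
    variables (correlation pruning, lifespan averaging, log-regression
    smoothing), to select among exhaustively enumerated candidate URFs by
    cross-validation, to project site index under climate-change scenarios
    across landscape grids, and to identify optimal seed sources for assisted
    migration. A synthetic-data module generates provenance trials and climate
    landscapes with known ground truth for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
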