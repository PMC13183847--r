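Package: grassyield
Title: Trait-Based Seed-Yield Modeling from UAV Imagery for Turfgrass Nitrogen Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for UAV-based seed-yield analysis in perennial turfgrass
    nitrogen trials. Generates synthetic randomized-complete-block field
    experiments and matching five-band reflectance and height (DSM/DEM)
    raster scenes; extracts plot-level plant height and vegetation indices
    with Otsu soil masking; estimates canopy nitrogen concentration with
    stage-specific random forests; fits a coupled quadratic source-sink
    yield response model and partitions trait contributions by grouped
    hierarchical (LMG) variance decomposition; and evaluates cross-year
    model transferability against a direct spectral baseline with
    agreement metrics (R2, NRMSE, NSE, Lin's CCC) and Fisher's protected
    LSD treatment separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
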