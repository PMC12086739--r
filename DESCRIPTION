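Package: dwscreen
Title: Cumulative Contaminant-Mixture Screening for Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonized cumulative screening of drinking-water
    contaminant-mixture exposures across private tapwater, public-supply
    tapwater, and bottled water. Computes apical-benchmark toxicity
    quotients and their per-sample concentration-addition sums (hazard
    index), bioactivity exposure-activity ratios against ToxCast-style
    activity concentrations at cutoff, toxicokinetically adjusted
    exposure-activity ratios via a steady-state three-compartment
    reverse-dosimetry model with Monte Carlo population variability, and
    one-way PERMANOVA comparisons of supply groups. Includes a synthetic
    exposure-data generator with known ground truth for end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
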