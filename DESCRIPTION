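Package: mcrscreen
Title: Maximum Cumulative Ratio Screening for Chemical Mixtures
Version: 0.1.0
Authors@R: person("mcrscreen", "developers", role = c("aut", "cre"),
    email = "mcrscreen@example.org")
Description: Screening-level cumulative risk assessment for chemical
    mixtures using the Maximum Cumulative Ratio (MCR). Computes per-sample
    Hazard Quotients, the Hazard Index, the maximum Hazard Quotient, MCR
    (the ratio of cumulative to maximum single-chemical toxicity) and the
    fraction of toxicity missed by a chemical-by-chemical assessment.
    Includes a generic drinking-water exposure scenario, a packaged table
    of chronic permitted doses for 81 pesticides and degradates, two
    left-censoring policies for non-detects (zero and DL/sqrt(2)),
    sample filtering and grouping, Kendall tau-b and Wilcoxon rank-sum
    trend statistics with tie handling, a synthetic monitoring-data
    generator emulating national surface-water survey structure, and a
    command-line workflow for assessment, simulation and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
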