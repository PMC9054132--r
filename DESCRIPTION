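Package: cinabc
Title: Quantifying Chromosomal Instability from Karyotype Diversity by
    Agent-Based Simulation and Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify chromosomal instability (CIN) from single-cell
    copy-number data. Provides an agent-based simulator of chromosome
    mis-segregation under explicit karyotype-selection models (gene abundance,
    driver density, hybrid, neutral) with exponential pseudo-Moran or
    constant-size Wright-Fisher population dynamics; phylogenetic and
    diversity summary statistics (aneuploidy, mean karyotype variance,
    Colless and Sackin imbalance, cherries, pitchforks) computed from
    copy-number profiles via Euclidean-distance complete-linkage trees; and
    rejection-sampling approximate Bayesian computation to infer the
    per-chromosome mis-segregation rate and selection strength from observed
    cell populations, with Bayesian selection-model comparison, sliding-window
    time-step tuning, and sample-size sufficiency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
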