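Package: igsim
Title: Simulation of Serum IgG Pharmacokinetics for Subcutaneous Immunoglobulin Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based simulation of serum total immunoglobulin G (IgG)
    pharmacokinetics in patients with primary immunodeficiency diseases who
    switch from stable intravenous immunoglobulin to weekly subcutaneous
    (SCIG) or every-4-week facilitated subcutaneous (fSCIG) therapy. Provides
    a stratified virtual-population generator with body-mass-index and
    lean-body-mass covariates, a two-compartment disposition model with
    first-order subcutaneous absorption, endogenous IgG synthesis and
    allometric lean-body-mass scaling solved analytically by superposition,
    steady-state exposure metrics (AUC, Cmax, Cmin, Cave), trough-threshold
    attainment, anchor-based calibration of the packaged parameter set, and
    stratified summary tables, percentile concentration-time ribbons and
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
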