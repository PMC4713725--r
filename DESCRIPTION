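Package: spinedyn
Title: Longitudinal Dendritic Spine Dynamics: Simulation, Tracking and Turnover Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying structural plasticity of dendritic spines in
    longitudinal two-photon imaging experiments. Provides a stochastic
    birth-death simulator of spine dynamics along dendrites (with full ground
    truth, so every downstream stage is testable), positional matching of
    spine annotations across weekly imaging sessions under the 0.5 micrometre
    same-spine rule, turnover and survival metrics (density per dendritic
    length, normalized formation/elimination, preexisting- and gained-spine
    survival, transient fraction), and the group-comparison statistics used in
    this field: extra sum-of-squares F tests on line fits, one-way ANOVA with
    the Newman-Keuls (Studentized range) post test, and two-tailed Student t
    tests. An end-to-end report command reproduces the standard panel
    structure (relative density, elimination, formation, survival curves) on
    simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr
Config/testthat/edition: 3
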