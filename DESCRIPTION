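Package: mgfabm
Title: Fuzzy Agent-Based Modeling of Mesenchymal Stem Cell Growth and
    Osteogenic Differentiation under Magnesium Ion Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lattice-based stochastic agent model of mesenchymal stem cell
    (MSC) populations in culture, in which each cell's decisions
    (proliferation, mortality, migration, osteogenic differentiation) are
    governed by a Mamdani-type fuzzy-logic controller driven by magnesium ion
    concentration, alkalinity, BMP2, TGF-beta1, cell density, maturity and DNA
    damage. Growth factors follow reaction-diffusion dynamics with cellular
    production, consumption, degradation and medium changes. Includes an
    iterative calibration engine combining two-level fractional-factorial
    sensitivity screening with ANOVA ranking and rejection approximate
    Bayesian computation, plus a synthetic-study generator that emulates
    typical cell-culture measurement schedules for download-free parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
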