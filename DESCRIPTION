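Package: atworkforce
Title: Needs-Based Estimation of the Global Assistive Technology Provision Workforce
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for needs-based planning of the assistive technology
    provision workforce. Extrapolates a reference country's workforce from
    regional full-time-equivalent tables, converts household-survey summaries
    into per-country counts of people needing assistive products with exact
    binomial confidence intervals, fits a fourth-root-scale Bayesian linear
    mixed model of need prevalence on median age and the Human Development
    Index to predict needs in unsurveyed countries, and scales the reference
    workforce by the global-to-reference need ratio with interval propagation
    and a deterministic productivity sensitivity analysis. Includes a synthetic
    world generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
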