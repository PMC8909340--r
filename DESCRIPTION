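Package: pmcohort
Title: Lifetime Markov Cohort Model of Ambient Fine Particulate Matter Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 13-state annual-cycle Markov cohort model projecting lifetime
    healthcare costs, quality-adjusted life years and life years for adult
    women under alternative ambient PM2.5 exposure concentrations. Disease
    incidence and case fatality respond to exposure through log-linear
    relative-risk scaling per concentration increment. Unprinted ancillary
    inputs (other-cause mortality, age-specific baseline utility) are supplied
    by a Gompertz-Makeham hazard and a declining utility template calibrated to
    published life-year and QALY anchors. Includes deterministic base-case
    analysis, one-way sensitivity analysis with tornado summaries, second-order
    Monte Carlo probabilistic sensitivity analysis, epidemiological validation
    rates, a synthetic parameter generator and a microsimulation cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
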