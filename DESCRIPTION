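Package: vapersim
Title: Cohort Simulation of the Population Health Impact of Nicotine Vaping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-based discrete-time simulator that compares a
    counterfactual projection of cigarette smoking in the absence of nicotine
    vaping products (NVPs) against a scenario in which vaping initiation,
    switching from smoking, and vaping cessation are active. Country inputs
    (population projections, overall mortality, life expectancy, smoking
    prevalence) are rescaled against built-in reference rates; outcomes are
    smoking- and vaping-attributable deaths and life-years lost, their net
    impact between scenarios, one-at-a-time sensitivity grids, and relative-
    change validation against survey series. Includes a synthetic input
    generator and an individual-level microsimulation oracle for testing.
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
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
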