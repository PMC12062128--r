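Package: egflux
Title: Constraint-Based and Physiological Analysis of Ethylene Glycol
    Co-Metabolism in Rhodotorula toruloides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced core stoichiometric model of Rhodotorula toruloides
    central carbon metabolism with a curated ethylene glycol (EG) oxidation
    pathway (NAD- and NADP-dependent dehydrogenase variants), a linear
    programming engine for flux balance analysis, parsimonious FBA, flux
    variability analysis and seeded random sampling of the near-optimal flux
    space, quantitative batch-fermentation physiology calculus (growth rates,
    phase detection, specific rates, yields, carbon balance, respiratory
    quotient, media stoichiometry), and a seeded generator of two-phase
    (exponential then nitrogen-limited) synthetic batch cultures used to
    exercise and validate the estimators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
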