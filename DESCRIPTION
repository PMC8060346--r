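Package: captopbpk
Title: Minimal PBPK Drug-Disease Modeling of Captopril in Renal and Heart
    Failure Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A minimal physiologically based pharmacokinetic (PBPK) model of
    captopril with a first-order absorption depot, a systemic compartment
    and a single adjusting compartment, parameterized from published
    drug-specific inputs. Predicts steady-state volume of distribution and
    tissue-to-plasma partition coefficients by the Rodgers-Rowland method
    (acid branch), simulates virtual-population trials in healthy,
    geriatric, chronic kidney disease and chronic heart failure populations
    using published disease scaling factors (hepatic clearance, Vss, organ
    blood flows), extracts PK parameters by non-compartmental analysis, and
    evaluates predictions with observed/predicted ratios, fold errors,
    average fold error, t-based confidence intervals, twofold checks and
    visual-predictive-check summaries against packaged observed PK tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
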