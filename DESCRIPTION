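Package: stentflow
Title: Balloon Deflation Strategy in Primary PCI: Trial Statistics and
    Gap-Flow Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how the velocity of stent-balloon deflation
    during primary percutaneous coronary intervention affects coronary
    flow.  Provides a seeded synthetic-cohort generator emulating a
    two-arm randomized balloon-deflation trial in ST-elevation
    myocardial infarction (corrected TIMI frame counts, cardiac-enzyme
    release curves, 30-day event times); the trial statistics (Pearson
    and exact 2x2 tests, Welch and pooled t-tests from raw or summary
    data, trapezoidal enzyme-release area under the curve, Kaplan-Meier
    curves for the major-adverse-cardiac-event composite, and the
    design-stage sample-size formula); and a quasi-one-dimensional
    lubrication model of the transient flow and wall shear stress in
    the thin annular gap between a deflating balloon and the vessel
    wall, used to compare deflation-velocity scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
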