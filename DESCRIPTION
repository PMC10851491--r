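Package: holcmod
Title: Case-Crossover Analysis of Effect Modification by Historical Redlining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-stratified bidirectional case-crossover analyses of
    short-term PM2.5 and extreme-heat mortality risk and their modification by
    residence in historically redlined (HOLC grade D) neighbourhoods. Includes
    population-threshold apportionment of HOLC security-map grades to Census
    block groups, grid-to-block-group exposure aggregation (population- and
    areal-weighted), locally defined extreme-heat and heat-wave calendars,
    referent sampling within month and day-of-week strata, a conditional
    logistic regression fitter with interaction terms and natural cubic spline
    adjustment, and a seeded synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
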