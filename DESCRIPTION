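Package: growthgains
Title: Schooling and Lifetime-Earnings Gains from Improved Linear Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects two non-health benefits of reduced child stunting in
    low- and middle-income countries: additional years of schooling and the
    net present value of additional lifetime earnings, per country and per
    birth cohort. Couples height-for-age z-score (HAZ) category
    distributions for 12-23-month-old children under baseline and
    counterfactual scenarios (including the SDG 2.2 stunting-target ramp)
    with Mincerian returns to schooling, GNI-per-capita-based wages, and
    long-run income-growth projections. Includes regional/income-group
    median imputation for missing country indicators, a synthetic data
    generator, report tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
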