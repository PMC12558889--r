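Package: equipanel
Title: Equity Analysis of Regional Health Workforce Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the equity of health human resource
    allocation across regions from long-format staffing panels. Implements
    the grouped (Lorenz-polygon) Gini coefficient with fairness bands, the
    decomposable Theil index with between- and within-province components
    and contribution rates, health resource and population agglomeration
    degrees (HRAD, PAD) with equity verdicts, descriptive staffing
    indicators (growth rates, physician-to-nurse ratios, rates per 10,000
    population), and linear year-trend regression on any fairness
    indicator. Includes a seeded synthetic province-to-prefecture panel
    generator so every pipeline stage can be exercised and validated
    without external yearbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
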