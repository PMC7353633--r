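Package: milkscreen
Title: Anomaly Screening for Adulterated UHT Milk from FTIR Compositional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens ultra-high-temperature (UHT) processed milk for quality and
    fraud anomalies from seven routine compositional features (protein, fat,
    total solids, solids-non-fat, lactose, density, freezing-point depression).
    Provides univariate percentile boundaries on measured and variance-adjusted
    control data, one-class classifiers (k-nearest neighbours, SIMCA, one-class
    SVM) with repeated leave-30%-out threshold calibration, a mass-balance
    simulator for single and combined milk adulterations (protein-rich powders,
    nitrogen compounds, carbohydrates, preservatives, water), consensus
    flagging of market-survey samples, per-area prevalence summaries, and
    principal component regression of prevalence on fraud-vulnerability factor
    ranks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
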