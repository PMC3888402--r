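Package: conflictdyn
Title: Dwell-Time and Fluctuation Analysis of Dyadic Conflict Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the moment-to-moment dynamics of dyadic
    conflict conversations coded at one-second resolution. Behavior streams
    (proself / neutral / prosocial state codes) are analyzed through dwell-time
    extraction, multi-bin-size probability density estimation, and least-squares
    comparison of single-exponential, power-law, and stretched-exponential
    models, including the effective kinetic rate constant implied by each fit.
    Emotional-valence streams (bounded integer pixel traces) are analyzed
    through Hurst rescaled-range analysis with shuffle surrogates, power
    spectral density tail slopes by four estimators, slope-to-Hurst conversion,
    and mean-split dichotomization. Group differences are assessed with an
    exact or tie-corrected Mann-Whitney U test. A deterministic synthetic-data
    generator (semi-Markov state switching with stretched-exponential dwell
    times; bounded random-walk or fractional-Gaussian-noise valence traces)
    makes every stage testable, and a pipeline orchestrates simulation,
    validation, analysis and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
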