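Package: rankshift
Title: Temporal Comparison of Community Rank-Abundance Structure from
    Repeated Pitfall-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how ground-dwelling arthropod
    assemblages change between repeated standardized surveys of the same
    sites. Raw pitfall-trap catches are pooled and standardized to annual
    activity density; species richness is estimated by individual-based
    rarefaction and an incidence-based bootstrap estimator with
    percentile confidence intervals; rank-abundance distributions are
    fitted by Poisson maximum likelihood under five classical
    species-abundance models (broken stick, niche preemption,
    lognormal, Zipf, Zipf-Mandelbrot) and compared by AIC; assemblages
    are compared by Renkonen percentage similarity, chord-distance
    minimum-variance clustering, species turnover accounting, and the
    Index of Rank-abundance Change (IRC), the mean absolute shift in
    species rank order between two samples. A synthetic-data generator
    emulates paired before/now trap surveys with trait-dependent
    turnover so every estimator can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
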