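Package: leisuretrips
Title: GPS-Determined Transport of Children in Leisure Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes combined GPS and accelerometer 15-second epoch data into
    travel behaviour of children in leisure time. Detects trips as continuous
    periods of movement tolerating short stationary pauses, classifies transport
    mode (walking, cycling, passive) from speed bands, applies wear-time and
    valid-day inclusion rules, restricts trips to leisure time with geofence-based
    exclusion of home-school commutes, and computes trips/day and minutes/day
    outcomes stratified by week- and weekend-days. Provides concurrent-validity
    statistics against travel diaries (Pearson correlations, paired t-tests),
    scoring of parental neighbourhood-environment questionnaires (seven
    walkability subscales including a weighted residential-density score), and
    association models between environment scores and transport outcomes:
    Gaussian-identity and Gamma-log mixed models and two-part hurdle models with
    class-level random intercepts fitted by adaptive Gauss-Hermite quadrature.
    Includes a synthetic-study generator with a ground-truth manifest so the
    whole chain is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    geosphere,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
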