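Package: vapescope
Title: Lexicon-Based Surveillance of Vaping Locations in Social-Media Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An infodemiology pipeline for location surveillance of
    vaping-related posts from a Twitter-style stream. Provides JSON-lines
    corpus readers and writers, a synthetic corpus generator with planted,
    labeled contamination and a known location-category mixture, an
    exclusion cascade (retweets, non-English posts, bot and high-frequency
    accounts, duplicates, promotional posts) with per-stage attrition
    reports, deterministic text normalization with rule-based
    lemmatization, rule-based multi-label classification of posts into
    eleven location categories via keyword dictionaries, and prevalence
    tables with Wilson 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
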