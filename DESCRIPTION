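Package: artakit
Title: Age-Related Typical Audiograms, Hearing-Loss Progression and
    Segregation-Based Variant Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of autosomal dominant
    progressive hearing loss. Builds age-related typical audiograms (ARTA)
    by cross-sectional linear regression of pure-tone thresholds on age,
    estimates annual threshold deterioration (ATD) per frequency, summarises
    ARTA grids as threshold feature arrays (counts of grid points by
    hearing-loss degree and frequency band) and compares variant-specific
    patterns with a chi-square goodness-of-fit test. A variant-evidence layer
    evaluates population rarity (PM2), counts informative co-segregation
    meioses on pedigrees (PP1) and combines ACMG criteria into a
    classification. A seeded synthetic-cohort generator produces
    multigenerational dominant families with progressive audiograms so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
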