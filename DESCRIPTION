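Package: sempgs
Title: Parental Effects from Transmitted and Nontransmitted Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural equation modeling of parent-offspring data using
    transmitted and nontransmitted haplotypic polygenic scores to separate
    direct genetic effects, genetic nurture, and vertical transmission while
    accounting for assortative mating through a copath parameter. Includes a
    forward-time family simulator (Gaussian-score and allele-level modes), a
    phased-trio haplotypic scorer, closed-form and path-enumeration model
    expectations, full-information maximum likelihood fitting over arbitrary
    missingness patterns, and the classic transmitted/nontransmitted
    regression estimator as a baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
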