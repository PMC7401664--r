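Package: warmbloodsim
Title: Stochastic Simulation of Riding-Horse Breeding Programs with Health Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a German Warmblood riding-horse
    breeding program with overlapping generations and an age-structured selection
    cascade (foal show, studbook registration, mare performance test, stallion
    licensing, 14-day and 50-day performance tests). Simulates 22 correlated
    performance traits together with two binary osteochondrosis dissecans (OCD)
    liability traits and height at withers on a 50k SNP genome with purely additive
    pleiotropic QTL. Provides multi-trait pedigree BLUP and single-step GBLUP
    breeding value estimation with Henderson's mixed model equations, a
    Meuwissen-Luo pedigree inverse, a VanRaden genomic relationship matrix,
    threshold and index selection scenarios against OCD, EBV-dependent stallion
    usage frequencies, and replicate-level trend reporting of OCD prevalence,
    genetic gain, kinship and estimation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
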