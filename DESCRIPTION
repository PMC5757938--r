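Package: wflm
Title: Weighted Functional Linear Models for Region-Based Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene- and region-based association testing of quantitative traits
    with weighted functional linear models. Genotypes and their effects along a
    genomic region are expanded in B-spline or Fourier bases, variants are
    weighted by beta-density functions of minor-allele frequency, and fixed
    genetic effects are tested with an F-statistic under a polygenic linear
    mixed model for both unrelated and family samples. Includes a simulation
    framework (population and pedigree genotypes, gene-dropping, trait models)
    for type-I error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
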