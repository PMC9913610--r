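Package: refficiency
Title: Quantitative Genetics of Reproductive Efficiency in Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse reproductive efficiency (Re) of beef cows from
    calving records: pedigree bookkeeping with Meuwissen-Luo inbreeding and
    sparse inverse numerator relationship matrices, REML estimation of
    repeatability and Legendre random-regression animal models, covariance
    function arithmetic (parity-specific heritabilities, genetic correlations
    and expected genetic values), a principal-component composite selection
    index, and a univariate linear-mixed-model genome-wide association scan
    with Wald tests on the index pseudo-phenotype. Includes a synthetic-data
    generator (pedigree, phenotypes, PLINK-1 genotypes) with a truth ledger
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
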