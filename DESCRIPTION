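Package: mpsdesign
Title: Two-Stage Study Design Simulation for Family-Based Sequencing of
    Complex Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-stage massively parallel sequencing (MPS) study
    designs for complex human disease. Stage I sequences one to three
    affected members of high-risk pedigrees and filters candidate genes by
    rare-variant type, within-pedigree concordance, and recurrence across
    pedigrees; stage II validates surviving genes by screening a larger
    panel of pedigrees with a binomial qualifying-variant criterion. The
    package provides exact pedigree carrier-probability computation
    (Elston-Stewart style peeling over a single diallelic locus),
    identity-by-descent sharing and gene-dropping algebra for background
    variant concordance, Monte Carlo simulation of stage-I filtering
    strategies across genetic architectures, analytic stage-II power and
    type-I error, and a study cost model, so that competing designs can be
    compared by expected true-gene yield, false-gene burden, and cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
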