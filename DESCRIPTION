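Package: clonosim
Title: Simulation of Karyotype Diploidization and Admixture Inference in
    Clonopsis Stick Insects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the reticulate origin of Clonopsis stick-insect
    parthenogens and androgenetic males. Provides exact and Monte-Carlo
    simulation of trivalent 2:1 segregation during meiosis of a triploid
    female, anaphasic restitution and the resulting egg karyotypes
    (cn = 72 and cn = 54 parthenogens, cn = 53 and cn = 35 androgenetic
    males), hybridization and androgenesis scenarios with mitochondrial
    lineage tracking, a synthetic generator for dominant AFLP
    presence/absence matrices with parental populations and admixed
    hybrids, and maximum-likelihood admixture inference for dominant
    diploid-scored markers with Evanno-style selection of the number of
    source populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
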