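Package: fawpopgen
Title: Invasion Genomics Inference for Fall Armyworm Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis toolkit for inferring the origin and adaptive
    evolution of invasive fall armyworm (Spodoptera frugiperda)
    populations from whole-genome resequencing data. Implements molecular
    strain typing from TPI and mitochondrial COX1 markers (Kimura
    2-parameter distances, BIO-NJ trees, bootstrap consensus), genotype
    principal component analysis, Weir-Cockerham F_ST with a permutation
    significance test, windowed absolute divergence (D_XY),
    transversion-weighted individual-level distance phylogenies, and a
    composite-likelihood selective-sweep scan from the site frequency
    spectrum. A hierarchical Balding-Nichols genotype simulator generates
    synthetic cohorts with the demographic structure of the study design
    so the full inference chain is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
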