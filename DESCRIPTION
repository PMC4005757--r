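Package: popstruct
Title: Uniparental-Marker Population Structure, Dating and Admixture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for uniparental (Y-chromosome and mtDNA)
    population surveys: haplogroup frequency tables with lineage collapsing,
    gene- and haplotype-diversity indices, hierarchical AMOVA with Phi
    statistics and permutation tests, Reynolds/Phi-ST/R-ST distance matrices
    and Mantel correlation with geography, spatial PCA maximising the product
    of variance and Moran's I with global/local permutation tests,
    DAPC posterior-membership (admixture-like) barplot tables, Gaussian-mixture
    cluster detection, Y-STR variance (SD) and mtDNA rho-statistic TMRCA
    estimation, and moment-based (mY) admixture-proportion estimation with
    bootstrap dispersion. A synthetic-data generator produces genotype tables
    with known clines, genealogies and admixture proportions so that every
    stage can be validated without access to the original samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    geosphere,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
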