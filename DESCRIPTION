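Package: snpsom
Title: Self-Organizing Map Portrayal of Genome-Wide SNP Genotype Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms biallelic SNP genotype matrices into excess
    minor-allele-frequency (eMAF) scores, self-organizes SNP profiles into a
    two-dimensional meta-SNP landscape, and portrays each accession as a grid
    image of its genome. Downstream tools segment the landscape into spots of
    correlated SNPs, associate categorical phenotypes through ANOVA and
    point-biserial correlation maps, derive accession-level diversity topology
    (correlation networks, PCA, minimum spanning trees, hierarchical trees,
    cluster-stability redistribution), and estimate branched flood pseudotime
    over k-nearest-neighbour graphs. A Balding-Nichols genotype simulator with
    dissemination-tree population structure provides ground-truthed fixtures
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    ape,
    jsonlite,
    generics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
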