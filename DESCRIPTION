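Package: gynolin
Title: Clonal Lineage Inference and Population Genetics for Gynogenetic
    Hybrid Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers clonal hybrid lineages from multi-ploidy microsatellite
    genotypes in sperm-dependent (gynogenetic) hybrid complexes, such as the
    Chrosomus eos-neogaeus fish system. Provides stepwise-mutation-model
    clonal distances, single-linkage lineage calling with consensus
    genotypes and triploid resolution, neighbor-joining trees, lineage
    alpha/beta/gamma diversity with local contributions to beta diversity
    (LCBD), Mantel tests and Mantel correlograms with progressive Holm
    correction, classical population-genetic statistics for the sexual host
    (Nei gene diversity, Hardy-Weinberg and linkage-disequilibrium
    permutation tests, Weir-Cockerham theta, Michalakis-Excoffier rho_ST
    with allele-size permutation tests, hierarchical AMOVA, Cavalli-Sforza
    and Edwards chord distances, PCA), and frequency-based assignment of
    hybrid haplomes to candidate source populations. A seeded synthetic-data
    generator reproduces the statistical structure these analyses assume and
    supplies ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
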