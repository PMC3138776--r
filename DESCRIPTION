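Package: ethnophylo
Title: Phylogenetic Signal and Hot-Node Detection in Ethnomedicinal Plant Use
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Community-phylogenetic tools for cross-cultural ethnobotany.
    Builds "communities" of taxa that share a medicinal-use category, tests
    each community for phylogenetic clumping with mean pairwise distance
    (MPD) and mean nearest taxon distance (MNTD) against permutation nulls,
    and locates "hot nodes" whose descendant tips are significantly
    overabundant in a use category (a nodesig-style enrichment test with an
    exact hypergeometric counterpart). Includes a Yule-tree and clumped
    community simulator for type-I error and power calibration, readers for
    long-form use records, wide presence matrices and Phylocom-style sample
    files, and annotated-Newick reporting of enriched clades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
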