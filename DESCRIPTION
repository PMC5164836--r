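Package: redphylo
Title: Coalescent Species Trees and Metabolic Pathway Loss Mapping for Red Algal Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A phylogenomic pipeline for inferring species trees of
    Rhodophyta (red algae) and mapping metabolic gene losses onto them.
    Provides single-copy orthogroup filtering from OrthoMCL-style cluster
    files, supermatrix concatenation with partition export, a maximum
    pseudo-likelihood species-tree estimator from rooted gene-tree triple
    frequencies under the multispecies coalescent, a two-level (gene and
    site) nonparametric bootstrap with majority-rule consensus, Dollo
    parsimony mapping of gene presence/absence characters (e.g. mevalonate
    pathway enzymes), and simulators for coalescent gene trees and protein
    alignments used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
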