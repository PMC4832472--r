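Package: cellnem
Title: Clonal Lineage Tree Inference from Single-Cell Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers clonal lineage trees of a tumor from noisy binary
    single-cell somatic variant genotype matrices using a nested effects
    model likelihood. Cells are placed on a rooted tree of clones whose
    root is the unmutated normal; genotyping errors are modelled by global
    false positive and false negative rates, and mutation placements are
    marginalised over a uniform prior. Includes a three-step heuristic
    search (cell-tree search, latent clone detection via Bayes factors,
    cell clustering), posterior mutation placement and expected branch
    lengths, grid maximum-likelihood estimation of the error rates, a
    matched data simulator, and tree comparison metrics (pairwise cell
    shortest-path distance, V-measure, mutation order accuracy).
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
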