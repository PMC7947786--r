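Package: divcons
Title: Differential Conservation Analysis of Paralogous Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates candidate specificity-determining residues that separate
    two paralogous enzyme subfamilies, such as the Pup ligase PafA and the
    depupylase Dop of the prokaryotic pupylation system. Sequences are
    partitioned into subfamilies by a sequence-similarity network, each family
    is aligned with a guide-tree based progressive aligner and scored for
    per-column conservation (phylogenetically weighted Jensen-Shannon
    divergence binned into 1-9 grades), the two family alignments are mapped
    onto each other through a Kabsch superposition of reference structures,
    and mapped positions are classified as shared, uniquely conserved or
    differently conserved, with a spatial active-site distance filter.
    Selected positions are turned into reciprocal mutants, combinatorial
    segment libraries and single-reversion series. A synthetic-data module
    generates labelled two-family bundles with planted constraint classes and
    toy structures so that every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
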