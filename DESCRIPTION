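Package: phylodiscord
Title: Diagnosing Discordant Phylogenetic Signal in Multi-Locus Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing conflicting phylogenetic signal between
    nuclear ribosomal (ITS-like) and plastid loci in groups of closely
    related species. Detects intra-individual polymorphic sites (IPS) and
    additive polymorphic sites (APS) from IUPAC-coded alignments, computes
    Fitch parsimony statistics (tree length, consistency and retention
    indices) with heuristic and exhaustive searches, runs the incongruence
    length difference (ILD) permutation test, tabulates supporting-position
    split spectra, builds statistical-parsimony (TCS-style) haplotype
    networks under a fixed connection limit, performs RELL-based weighted
    Kishino-Hasegawa and Shimodaira-Hasegawa topology tests, and implements
    a posterior-predictive test for hybridization versus incomplete lineage
    sorting based on minimum inter-species sequence distances simulated
    under the multispecies coalescent. A synthetic-data generator produces
    complete two-locus study scenarios with known truth (ILS, hybridization
    pulses, ribotype mixing with tunable homogenization) so that every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    seqinr,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
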