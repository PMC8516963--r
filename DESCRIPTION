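Package: orthotrace
Title: Iterative Profile Search, Tiered Absence Verification and
    Phylogenetic Loss Mapping for Divergent Orthologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics pipeline for calling gene absences in
    highly divergent lineages. Builds position-specific log-odds profiles
    from seed alignments, calibrates E-values on random decoys with a
    Gumbel fit, and iterates taxa-enriched profile searches to
    convergence. Verifies candidate absences through a tiered cascade
    (proteome search, six-frame translated genome rescue, relaxed
    domain-level screening), assembles presence/absence matrices, maps
    losses onto a rooted species tree by Dollo parsimony, and computes
    genome-QC statistics (BUSCO-style completeness percentages, k-mer
    assembly completeness, allele-balance ploidy inference). Ships a
    synthetic genome/proteome evolution simulator that generates species
    trees with long-branch clades, protein families with lineage-specific
    losses, genomes with deliberate annotation failures, pileups and
    k-mer sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
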