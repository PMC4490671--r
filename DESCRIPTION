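Package: virosieve
Title: Curation of Virus Genome Scaffolds from Metagenomic Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to select genuine virus scaffolds from mixed (virus-size
    fraction) metagenomic assemblies. Pools contigs from multiple k-mer
    assemblies and removes redundant smaller contigs, detects circular
    genome scaffolds from discordantly mapped read pairs and terminal
    overlaps, classifies scaffolds as viral or cellular/plasmid/
    mitochondrial contamination from per-gene database-hit profiles,
    clusters circular genomes by Dice similarity over summed tblastx
    bitscores with neighbor-joining trees, assigns putative hosts through
    exact attP/tRNA matches gated on integrase presence, and cross-matches
    CRISPR spacers against the assembled virome. Includes a synthetic
    virome generator with planted ground truth so the whole pipeline is
    testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
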