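Package: barcodelim
Title: Multi-Method Species Delimitation from DNA Barcode Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits putative species (operational taxonomic units, OTUs)
    from aligned mitochondrial COI barcode sequences by running three
    independent single-locus engines -- Automatic Barcode Gap Discovery
    (ABGD), the single- and multiple-threshold General Mixed Yule-coalescent
    model (GMYC) on an ultrametric tree, and BIN-style refined single-linkage
    clustering with Markov-cluster refinement (RESL) -- then categorizes the
    three partitions into FULL MATCH, PARTIAL MATCH and DISCORDANT comparison
    units and resolves conflicts with a sympatry rule for sister OTUs,
    reporting diagnostic nucleotides and monophyly as an audit trail.
    Includes pairwise p/JC69/K2P distances, UPGMA and neighbor-joining guide
    trees, haplotype collapsing, a coalescent-within-Yule barcode data
    simulator with known truth, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ape,
    phangorn,
    igraph,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'seq-io.R'
    'distances.R'
    'abgd.R'
    'resl.R'
    'gmyc.R'
    'consensus.R'
    'resolution.R'
    'simulate.R'
    'pipeline.R'
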