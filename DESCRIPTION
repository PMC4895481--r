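Package: scaflink
Title: Comparative Gene-Order Scaffolding and Linkage-Map Consensus Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves fragmented draft genome assemblies using homology
    evidence from related genomes and genetic linkage maps. Conserved gene
    adjacencies across a set of reference genomes, weighted by phylogenetic
    proximity to the target, score candidate joins between scaffold
    extremities; a conflict-free set of joins is selected by exact
    maximum-weight matching and assembled into oriented super-scaffold
    chains. Chains are anchored into male and female linkage maps, the two
    maps are merged into a precedence graph, and per-chromosome consensus
    scaffold orders are produced by topological sorting. Includes standard
    assembly metrics (N50/N90, length composition) and a gene-order
    evolution simulator (inversions, translocations, indels, duplications
    along a phylogeny, assembly fragmentation and noisy linkage maps with
    ground truth) so the whole pipeline can be exercised and evaluated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
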