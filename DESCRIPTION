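Package: sdrmine
Title: Sequence-Directed Metagenome Mining for Short-Chain Dehydrogenases/Reductases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a sequence-directed
    metagenome mining workflow for short-chain dehydrogenase/reductase (SDR)
    carbonyl reductases: six-frame ORF discovery on assembled contigs with
    initiator-methionine/stop-codon/length filters, family search against
    seed enzymes by local alignment and a position-specific scoring profile,
    greedy dereplication of hits into a non-redundant panel, identity-matrix
    and neighbor-joining comparative views, catalytic-motif quality control,
    Gibson-assembly primer design with in-silico construct verification, and
    NAD(P)H-depletion plate-assay quantification. A seeded synthetic
    metagenome generator with planted, divergence-controlled family genes
    and shuffled decoys provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
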