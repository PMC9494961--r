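Package: mitoarch
Title: Comparative Architecture of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, motivated by the rearranged mitogenomes of
    rhacophorid tree frogs. Provides a validated container for circular
    genomes with strand-aware features; nucleotide composition, AT/GC
    skew and relative synonymous codon usage (RSCU) statistics; circular
    junction (spacer/overlap) accounting and named tRNA cluster
    detection; a tandem duplication-random loss (TDRL) model of gene
    rearrangement with exhaustive single-event inference; control-region
    tandem repeat detection, motif search and paralog identity; a
    neighbor-joining bootstrap test for concerted evolution of duplicated
    control regions; local-alignment detection of degraded gene remnants
    in non-coding regions with classification of ATP8-loss pathways; and
    a seeded synthetic mitogenome generator with ground-truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
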