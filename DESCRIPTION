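Package: orfgenesis
Title: Tracing the De Novo Origin of Protein-Coding Genes Across Genome Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of a recently born
    protein-coding gene from a reference-anchored multiple genome alignment
    of its coding sequence. Detects ORF-disrupting events per species
    (start-codon loss, frameshifting indels, premature and lost stop
    codons), converts them into protein-homology fractions, and places
    shared events on branches of a species phylogeny by parsimony. Also
    provides a Guigo codon-usage bias score with a reshuffling permutation
    test, NG86 Ka/Ks estimation with Monte-Carlo confidence intervals,
    promoter GC/motif characterisation with in-silico PCR, an
    expression-matrix association layer (correlation percentile screens,
    one-tailed Welch tests, two-way ANOVA), and a synthetic-data generator
    that evolves a CDS down a tree with scripted disruptions so that the
    whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Phylogenetics, ComparativeGenomics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
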