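Package: codonbalance
Title: Codon Demand and tRNA Anticodon Supply Across Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interface between the mRNA codon demand of
    a transcriptome and the tRNA anticodon supply measured by Pol III occupancy,
    across tissues and developmental stages. Computes expression-weighted codon
    and amino-acid usage from coding sequences, isoacceptor and isotype
    abundance from tRNA gene quantifications, wobble-corrected codon-anticodon
    rank correlations, shuffled-transcriptome null distributions, a
    within-family expression-compensation permutation test, genomic clustering
    of tRNA genes with randomization tests, and colocalization and
    chromatin-association tests. Includes a synthetic-data generator that
    emulates a two-tissue, multi-stage, replicated study design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    DESeq2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
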