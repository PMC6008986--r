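Package: regchar
Title: Characterization of 5' and 3' Regulatory Features of Gene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to characterize the regulatory landscape of a gene locus
    from sequence alone: scanning promoters for transcription factor binding
    sites defined as IUPAC degenerate consensus strings or JASPAR position
    frequency matrices, detecting CpG islands by the classic GC-content and
    observed/expected CpG criteria, profiling dinucleotide base-stacking
    energies along regulatory sequences, classifying promoters
    (TATA-containing, CpG-island-positive, bidirectional candidates), and
    analysing convergent transcript pairs for complementary heteroduplex
    segments and microRNA recognition elements by local alignment and seed
    matching. A seeded synthetic-sequence generator plants motifs, islands,
    complementary segments and expression effects with ground-truth records
    so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
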