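Package: astrolnc
Title: Screening of lncRNAs Inversely Correlated with Brain Perivascular Astrogliosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying long non-coding RNAs
    (lncRNAs) whose expression decreases monotonically with the severity of
    brain perivascular astrogliosis in an eight-sample microarray design.
    Provides confidence, biotype, replicate-outlier and low-expression
    filtering with Z-score standardization; principal component analysis over
    probes to rank lesion-suppressive candidates; extraction of consensus
    subsequences from a multiple alignment of the selected probe sequences;
    exhaustive reverse-complement scanning of an mRNA transcript database at a
    configurable identity threshold; and hypergeometric term-enrichment
    statistics (EASE-style one-sided test, Benjamini-Hochberg FDR, fold
    enrichment) for the matched gene sets. Includes a synthetic-data generator
    with planted ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
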