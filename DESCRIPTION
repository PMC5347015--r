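Package: coolseq
Title: No-Replicate RNA-Seq Differential Expression and Pathway Enrichment
    for Cooling-Rate Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain used in
    three-library (control / fast-cooled / slow-cooled) RNA-seq studies
    without biological replicates: FASTQ clean-read filtering, RPKM
    quantification, the Audic-Claverie exact two-library test with
    Benjamini-Hochberg FDR control and thresholded DEG calling,
    cross-contrast DEG set analysis, hypergeometric pathway
    over-representation with Bonferroni correction, and a four-type
    cross-contrast pathway classification.  A synthetic-data generator
    with planted ground truth makes every stage testable without any
    sequencing archive download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
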