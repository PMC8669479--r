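Package: cgprofiler
Title: Chemical Genomic Profiling of Pooled Barcoded Yeast Deletion Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled Bar-seq chemical genomic screens of
    barcoded Saccharomyces cerevisiae deletion libraries, used to identify
    xenobiotic importers and exporters. Implements barcode counting from
    amplicon FASTQ with Levenshtein-distance error correction, median-of-ratios
    normalization, negative-binomial likelihood-ratio tests of differential
    barcode abundance with Benjamini-Hochberg correction and threshold-based
    hit calling, PCA and profile correlation of compound responses, microplate
    growth-curve scoring with four-parameter-logistic IC90 estimation, and
    z-score resistance calling on quantified high-density colony arrays. A
    synthetic-data module generates pooled-competition reads, dose-response
    growth curves and colony-array images with known truth so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    Biostrings,
    png
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
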