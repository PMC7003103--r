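Package: barseqfit
Title: Competitive Fitness Estimation from Pooled Barcode Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled competitive-fitness (bar-seq) experiments in
    which strains carrying bipartite chromosomal barcodes are co-cultured
    through serial batch passages and their relative abundance is read out
    by amplicon sequencing. Includes a serial-batch competition simulator
    with a realistic measurement model (strain-specific DNA-extraction bias,
    multinomial sequencing noise, FASTQ emission), Hamming-distance barcode
    demultiplexing into strain-by-sample count matrices, median-of-ratios
    (RLE) normalization, per-strain negative-binomial quasi-likelihood GLM
    contrasts under a treatment-by-time cell-means design, and downstream
    reporting: tolerance classification, Ward.D2 fitness clustering,
    cross-batch rank correlation, and optical-density-to-cell-number
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    limma
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
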