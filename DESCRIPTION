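Package: lyscreen
Title: Pooled CRISPR Knockout Selection-Screen Analysis and Colocalization Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled genome-wide CRISPR knockout screens selected
    with the sphingomyelin-binding cytolysin lysenin: inline-barcode FASTQ
    demultiplexing, spacer extraction and sgRNA counting, per-sample read
    normalization to ten million, fold-enrichment with an explicit
    zero-denominator rule, and reproducible greater-than-fivefold dual
    half-library candidate-gene calling. Includes a selection-screen
    simulator with known ground truth (log-normal baseline, multi-round
    survival selection, multinomial sequencing sampling, FASTQ emission)
    and quantitative-imaging statistics for two-channel fluorescence
    micrographs: masked Pearson correlation, thresholded Manders
    colocalization coefficients, marker-mask binarization, masked mean
    intensity per area, and bilinear line profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    optparse,
    pracma,
    S4Vectors,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
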