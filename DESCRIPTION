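Package: pbmscan
Title: Transcription Factor Binding Site Prediction by Direct Mapping of
    Protein Binding Microarray E-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts transcription factor binding sites by mapping protein
    binding microarray (PBM) 8-mer enrichment scores (E-scores) directly onto
    genomic sequence and scoring each locus with a moving average of W
    overlapping octamers.  Includes readers and writers for UniPROBE-style
    8-mer tables, FASTA, BED6 and TRANSFAC matrices; thresholded site calling
    with interval merging; core-motif census, first-position histograms,
    dual-core orientation analysis and TSS-proximity enrichment; linear and
    nonlinear (Kd) regression of scores against binding measurements; and
    synthetic-data generators with ground-truth manifests for end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
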