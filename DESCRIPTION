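Package: dropforge
Title: Condensate-Enhanced Oligo Assembly and Digital Cell-Free Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for condensate-enhanced
    oligonucleotide assembly and digital cell-free gene expression.
    Provides seeded synthetic-data generators with embedded ground truth
    (phase-separated droplet images, femtoliter reactor arrays, FLIM decay
    histograms, oligo reads with synthesis errors, qPCR dilution series);
    droplet segmentation and partition-coefficient quantification with
    FLIM-based quantum-yield correction and gamma-corrected FRET;
    exponential qPCR standard-curve fitting with slope and amplification
    efficiency calculus; alignment-based synthesis-error spectra, clone
    classification, and a closed-form ligation-fidelity model with a
    Monte-Carlo cross-check; and digital reactor counting with
    Gaussian-model thresholds, multi-step false-positive filtering,
    pseudo-positive detection floors, and Poisson occupancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    Biostrings,
    EBImage,
    mclust,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
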