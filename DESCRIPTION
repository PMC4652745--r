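Package: ruvm
Title: Two-Stage Removal of Unwanted Variation for Differential
    Methylation Analysis of 450k-Style Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential methylation analysis for Illumina
    HumanMethylation450-style data in the presence of unwanted variation
    (batch effects, cell-composition shifts, sample mix-ups). Implements
    a two-stage RUV-inverse procedure: Stage 1 fits a generalized least
    squares model per CpG whose sample covariance is estimated from
    platform negative-control probes, and Stage 2 refits using
    empirically selected control probes drawn from the least associated
    CpGs. Per-feature standard errors are obtained by the inverse
    (random design column) method. Also provides M-value preprocessing
    and probe/sample filtering, Benjamini-Hochberg adjustment, an
    unadjusted moderated-t baseline, quality-control diagnostics (RLE,
    MDS, p-value histograms), ROC/AUC and cumulative true-positive
    ranking evaluation against user-supplied truth sets, a seeded
    synthetic-data generator with known ground truth, and a command-line
    interface over tab-delimited text files.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    limma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
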