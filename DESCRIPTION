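Package: gliomacnv
Title: Tumor-Fraction-Aware Copy-Number Profiling and Glioma CNV Marker
    Classification from Low-Pass Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns low-pass whole-genome long-read alignments (or precomputed
    binned read counts in fixed-step WIG) into tumor-fraction-aware
    copy-number calls and glioma-relevant marker statuses. Reads are counted
    in fixed 500-kb windows, corrected for GC and mappability bias,
    optionally normalized against a panel of normals, and segmented with a
    hidden Markov model whose emission centers depend jointly on integer
    copy state and tumor fraction; tumor fraction is estimated by likelihood
    maximization over a grid. An artificial-admixture regression calibrates
    the expected copy value of a homozygous CDKN2A/B deletion as a function
    of tumor fraction, so observed deletions can be classified as homozygous
    versus hemizygous. Per-marker calls (CDKN2A/B, EGFR, 1p, 19q,
    chromosomes 7 and 10) feed a deterministic WHO-CNS5-style rule engine
    producing a classification suggestion and grading hint, rendered with a
    genome-wide copy-number plot into a single self-contained HTML report.
    A seeded simulator generates negative-binomial bin counts with planted
    alterations at known tumor fraction for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glue,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rsamtools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
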