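Package: soloMeth
Title: Single-Sample Case-Control Analysis of Methylation Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects patient-specific hypomethylation of imprinted-like regions
    from HumanMethylation450-style array data when only one case is available.
    Implements quality filtering and normalisation of beta-value matrices
    (missing-value, detection p-value and sex-chromosome filters, logit M-value
    transformation, quantile normalisation and Infinium I/II peak correction),
    per-CpG single-case statistics against a small batch-matched control group
    (Crawford-Howell, one-sample and Weisberg t-tests), effect sizes with
    noncentral-t confidence intervals, and region-level calling of consecutive
    hypomethylated hemimethylated CpGs with Fisher-combined P values. Includes
    a seeded simulator of imprinted-DMR methylation datasets with known truth
    for power and control-group-size experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: DNAMethylation, MethylationArray, DifferentialMethylation,
    Epigenetics, QualityControl, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
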