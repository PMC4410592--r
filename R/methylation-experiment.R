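#' Build a MethylationExperiment
#'
#' Assembles a probe manifest, a beta-value matrix, a detection p-value matrix
#' and a case/control design into a validated container. Chromosome names are
#' normalised to the `"chrN"` dialect on ingestion (`"X"`, `"23"` and `"chrX"`
#' all become `"chrX"`), and probes are kept in manifest order throughout the
#' pipeline.
#'
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based) and `design_type` (`"I"` or `"II"`).
#' @param beta numeric matrix, probes x samples, values in \[0, 1\], `NA`
#'   allowed; rownames must match `manifest$probe_id`.
#' @param detectionP numeric matrix of the same shape as `beta`.
#' @param case character(1), the id of the single case sample.
#' @param controls character vector of control sample ids, or `"all-others"`
#'   (the default) to use every non-case sample.
#'
#' @return A [MethylationExperiment-class] object.
#' @examples
#' sim <- simulate450k(simulationConfig(nBackgroundProbes = 50, seed = 1))
#' sim$dataset
#' @export
MethylationExperiment <- function(manifest, beta, detectionP,
                                  case, controls = "all-others") {
    manifest <- as.data.frame(manifest)
    required <- c("probe_id", "chrom", "pos", "design_type")
    if (!all(required %in% colnames(manifest)))
        stop("manifest must have columns: ", paste(required, collapse = ", "))
    beta <- as.matrix(beta)
    detectionP <- as.matrix(detectionP)
    if (!is.null(colnames(beta)) && !is.null(colnames(detectionP))) {
        extra <- setdiff(colnames(beta), colnames(detectionP))
        missing <- setdiff(colnames(detectionP), colnames(beta))
        if (length(extra) || length(missing))
            stop("sample columns differ between beta and detectionP: ",
                 paste(c(extra, missing), collapse = ", "))
        detectionP <- detectionP[, colnames(beta), drop = FALSE]
    }
    if (!identical(dim(beta), dim(detectionP)))
        stop("'beta' (", paste(dim(beta), collapse = "x"),
             ") and 'detectionP' (", paste(dim(detectionP), collapse = "x"),
             ") must have identical dimensions")
    if (is.null(colnames(detectionP))) colnames(detectionP) <- colnames(beta)
    if (nrow(beta) != nrow(manifest))
        stop("beta has ", nrow(beta), " rows but manifest describes ",
             nrow(manifest), " probes")
    if (!is.null(rownames(beta))) {
        if (anyDuplicated(rownames(beta)))
            stop("duplicate probe ids in beta matrix: ",
                 paste(head(rownames(beta)[duplicated(rownames(beta))], 5),
                       collapse = ", "))
        if (!all(rownames(beta) %in% manifest$probe_id))
            stop("beta rows absent from manifest: ",
                 paste(head(setdiff(rownames(beta), manifest$probe_id), 5),
                       collapse = ", "))
        beta <- beta[manifest$probe_id, , drop = FALSE]
        detectionP <- detectionP[manifest$probe_id, , drop = FALSE]
    } else {
        rownames(beta) <- rownames(detectionP) <- manifest$probe_id
    }
    samples <- colnames(beta)
    if (!case %in% samples)
        stop("case sample '", case, "' not found in the matrices")
    if (identical(controls, "all-others")) {
        controls <- setdiff(samples, case)
    } else if (!all(controls %in% samples)) {
        stop("control samples not found: ",
             paste(setdiff(controls, samples), collapse = ", "))
    }
    keep <- c(case, setdiff(controls, case))
    beta <- beta[, keep, drop = FALSE]
    detectionP <- detectionP[, keep, drop = FALSE]

    chrom <- normalizeChromosome(manifest$chrom)
    rr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = as.integer(manifest$pos), width = 1L),
        probeID = as.character(manifest$probe_id),
        designType = as.character(manifest$design_type))
    names(rr) <- manifest$probe_id
    cd <- S4Vectors::DataFrame(
        role = ifelse(keep == case, "case", "control"),
        row.names = keep)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta, detectionP = detectionP),
        rowRanges = rr, colData = cd)
    new("MethylationExperiment", se)
}

## "chrX"/"X"/"23"/"chr23" -> "chrX"; autosomes get a "chr" prefix
normalizeChromosome <- function(chrom) {
    chrom <- as.character(chrom)
    chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
    chrom[chrom %in% c("23", "x")] <- "X"
    chrom[chrom %in% c("24", "y")] <- "Y"
    paste0("chr", chrom)
}

#' @rdname MethylationExperiment
#' @export
setMethod("betaValues", "MethylationExperiment", function(x)
    SummarizedExperiment::assay(x, "beta"))

#' @rdname MethylationExperiment
#' @export
setMethod("detectionP", "MethylationExperiment", function(x)
    SummarizedExperiment::assay(x, "detectionP"))

#' @rdname MethylationExperiment
#' @export
setMethod("mValues", "MethylationExperiment", function(x) {
    if (!"M" %in% SummarizedExperiment::assayNames(x))
        stop("no 'M' assay yet; run preprocess() first")
    SummarizedExperiment::assay(x, "M")
})

#' @rdname MethylationExperiment
#' @export
setMethod("probeManifest", "MethylationExperiment", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(probe_id = rr$probeID,
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               design_type = rr$designType,
               row.names = NULL)
})

#' @rdname MethylationExperiment
#' @export
setMethod("sampleRoles", "MethylationExperiment", function(x)
    setNames(SummarizedExperiment::colData(x)$role, colnames(x)))

#' @rdname MethylationExperiment
#' @export
setMethod("caseSample", "MethylationExperiment", function(x)
    colnames(x)[SummarizedExperiment::colData(x)$role == "case"])

#' @rdname MethylationExperiment
#' @export
setMethod("controlSamples", "MethylationExperiment", function(x)
    colnames(x)[SummarizedExperiment::colData(x)$role == "control"])

#' @rdname MethylationExperiment
#' @export
setMethod("show", "MethylationExperiment", function(object) {
    cat("MethylationExperiment with", nrow(object), "probes and",
        ncol(object), "samples\n")
    cat("case:", caseSample(object), " controls:",
        length(controlSamples(object)), "\n")
    cat("assays:",
        paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
    pp <- S4Vectors::metadata(object)$preprocessing
    if (!is.null(pp))
        cat("preprocessing steps applied:",
            paste(vapply(pp, `[[`, "", "step"), collapse = " -> "), "\n")
    invisible(NULL)
})
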