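## ---- probe/sample quality filters ------------------------------------------

record_step <- function(x, step, ...) {
    md <- S4Vectors::metadata(x)
    md$preprocessing <- c(md$preprocessing, list(list(step = step, ...)))
    S4Vectors::metadata(x) <- md
    x
}

#' Quality filters for methylation datasets
#'
#' The four filters applied ahead of normalisation:
#'
#' * `dropMissingProbes()` removes every CpG site with a missing beta value in
#'   any sample.
#' * `dropFailedSamples()` removes samples in which more than `sampleFrac`
#'   (default 90%) of probes have detection p-value above `pThreshold`
#'   (default 0.05). Both inequalities are strict. Losing the case sample
#'   aborts the analysis: it is undefined without it.
#' * `dropFailedProbes()` removes probes for which more than `probeFrac`
#'   (default 75%) of samples have detection p-value above `pThreshold`
#'   (default 1e-5).
#' * `dropSexChromosomes()` removes chrX and chrY probes to avoid sex bias
#'   (chromosome dialects are normalised at ingestion, so `"X"`, `"23"` and
#'   `"chrX"` manifests all behave the same).
#'
#' Every filter records its removal count in `metadata(x)$preprocessing` and
#' never reorders the retained probes.
#'
#' @param x a [MethylationExperiment-class].
#' @param pThreshold,sampleFrac,probeFrac filter thresholds in (0, 1).
#' @return The filtered `MethylationExperiment`.
#' @export
dropMissingProbes <- function(x) {
    keep <- rowSums(is.na(betaValues(x))) == 0L
    if (!any(keep))
        stop("empty dataset: every probe has a missing value")
    record_step(x[keep, ], "dropMissingProbes", removed = sum(!keep))
}

#' @rdname dropMissingProbes
#' @export
dropFailedSamples <- function(x, pThreshold = 0.05, sampleFrac = 0.90) {
    stopifnot(pThreshold > 0, pThreshold < 1, sampleFrac > 0, sampleFrac < 1)
    failFrac <- colMeans(detectionP(x) > pThreshold, na.rm = TRUE)
    drop <- failFrac > sampleFrac
    if (drop[colnames(x) == caseSample(x)])
        stop("case sample '", caseSample(x), "' fails detection-p QC (",
             round(100 * failFrac[caseSample(x)], 1),
             "% of probes above p = ", pThreshold,
             "); single-sample analysis is undefined without the case")
    record_step(x[, !drop], "dropFailedSamples", removed = sum(drop),
                samples = colnames(x)[drop])
}

#' @rdname dropMissingProbes
#' @export
dropFailedProbes <- function(x, pThreshold = 1e-5, probeFrac = 0.75) {
    stopifnot(pThreshold > 0, pThreshold < 1, probeFrac > 0, probeFrac < 1)
    failFrac <- rowMeans(detectionP(x) > pThreshold, na.rm = TRUE)
    keep <- !(failFrac > probeFrac)
    if (!any(keep))
        stop("empty dataset: every probe fails detection-p QC")
    record_step(x[keep, ], "dropFailedProbes", removed = sum(!keep))
}

#' @rdname dropMissingProbes
#' @export
dropSexChromosomes <- function(x) {
    chrom <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(x)))
    keep <- !chrom %in% c("chrX", "chrY")
    record_step(x[keep, ], "dropSexChromosomes", removed = sum(!keep))
}

## ---- beta <-> M ------------------------------------------------------------

#' Logit (base 2) transform between beta and M values
#'
#' M = log2(beta / (1 - beta)), the variance-stabilised scale on which all
#' tests are run. Betas are clamped into \[eps, 1 - eps\] first so the
#' boundary values 0 and 1 map to finite M; on the open interval the two
#' functions are exact inverses. Hemimethylation (beta = 0.5) maps to M = 0.
#'
#' @param beta,m numeric vector or matrix.
#' @param eps clamping bound, default 1e-6.
#' @return Transformed values of the same shape.
#' @examples
#' betaToM(c(0.5, 2/3, 1/3))  # 0, 1, -1
#' mToBeta(betaToM(0.26))
#' @export
betaToM <- function(beta, eps = 1e-6) {
    b <- pmin(pmax(beta, eps), 1 - eps)
    log2(b / (1 - b))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
    1 / (1 + 2^(-m))
}

## ---- quantile normalisation ------------------------------------------------

#' Quantile-normalise an M-value matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' row-wise mean of the sorted columns, preserving within-column rank order;
#' ties share the mean of the reference values at their rank positions.
#' Idempotent, and a no-op (with a warning) on a single-sample matrix.
#'
#' @param m numeric matrix, probes x samples, no missing values.
#' @return The normalised matrix, same dimnames.
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m))
        stop("quantileNormalize() requires a complete matrix; ",
             "run dropMissingProbes() first")
    if (ncol(m) < 2L) {
        warning("single-sample matrix: quantile normalisation is the identity")
        return(m)
    }
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

## ---- Infinium I/II peak correction -----------------------------------------

## KDE mode of x restricted to one side of zero; NA when the stratum is
## too thin to support a density estimate
density_mode <- function(x, side = c("neg", "pos")) {
    side <- match.arg(side)
    x <- x[if (side == "neg") x < 0 else x > 0]
    if (length(x) < 10L) return(NA_real_)
    d <- density(x, bw = "nrd0")
    d$x[which.max(d$y)]
}

#' Correct Infinium II peak compression
#'
#' Type II probes have a compressed dynamic range relative to type I. Per
#' sample, the unmethylated (M < 0) and methylated (M > 0) density modes of
#' each design-type stratum are located by kernel density estimation
#' (Silverman's rule bandwidth), and type II M values are rescaled so their
#' modes land on the type I modes: negative values are multiplied by
#' modeI_unmeth / modeII_unmeth and positive values by
#' modeI_meth / modeII_meth. Type I values are never changed, the rescaling
#' never flips signs, and hemimethylated probes near M = 0 move by at most
#' the mode-scaling factor. Samples in which either stratum lacks a
#' detectable mode on either side are left uncorrected with a warning.
#'
#' @param m numeric matrix of M values, probes x samples.
#' @param designType character vector, `"I"`/`"II"` per probe (row).
#' @return The corrected matrix.
#' @export
peakCorrect <- function(m, designType) {
    m <- as.matrix(m)
    if (length(designType) != nrow(m))
        stop("'designType' must have one entry per probe row")
    isII <- designType == "II"
    if (!any(isII) || all(isII)) {
        warning("need both design types to peak-correct; returning input")
        return(m)
    }
    out <- m
    skipped <- character(0)
    for (j in seq_len(ncol(m))) {
        mi <- m[!isII, j]
        mii <- m[isII, j]
        modes <- c(iU = density_mode(mi, "neg"), iM = density_mode(mi, "pos"),
                   iiU = density_mode(mii, "neg"), iiM = density_mode(mii, "pos"))
        if (anyNA(modes) || modes["iiU"] >= 0 || modes["iiM"] <= 0) {
            skipped <- c(skipped, colnames(m)[j] %||% as.character(j))
            next
        }
        v <- mii
        v[v < 0] <- v[v < 0] * (modes["iU"] / modes["iiU"])
        v[v > 0] <- v[v > 0] * (modes["iM"] / modes["iiM"])
        out[isII, j] <- v
    }
    if (length(skipped))
        warning("peak correction skipped for sample(s) without two density ",
                "modes per stratum: ", paste(skipped, collapse = ", "))
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- the pipeline ----------------------------------------------------------

#' Pre-process a methylation dataset
#'
#' Runs the full quality-control and normalisation pipeline in its fixed
#' order: missing-value removal, sample detection-p QC, probe detection-p QC,
#' sex-chromosome removal, beta-to-M transformation, quantile normalisation
#' and Infinium I/II peak correction. The result carries the normalised M
#' values as an `M` assay; the `beta` assay keeps the filtered raw betas.
#' Each step's removal count is logged in `metadata(x)$preprocessing`. No
#' batch correction is performed: the design assumes the case and its
#' controls come from the same array batch.
#'
#' @param x a [MethylationExperiment-class].
#' @param samplePThreshold,sampleFrac sample QC thresholds (see
#'   [dropFailedSamples()]).
#' @param probePThreshold,probeFrac probe QC thresholds (see
#'   [dropFailedProbes()]).
#' @param quantile,peak logical switches for the two normalisation steps.
#' @return The processed `MethylationExperiment` with an added `M` assay.
#' @examples
#' sim <- simulate450k(simulationConfig(nBackgroundProbes = 300, seed = 7))
#' me <- preprocess(sim$dataset)
#' me
#' @export
preprocess <- function(x, samplePThreshold = 0.05, sampleFrac = 0.90,
                       probePThreshold = 1e-5, probeFrac = 0.75,
                       quantile = TRUE, peak = TRUE) {
    x <- dropMissingProbes(x)
    x <- dropFailedSamples(x, samplePThreshold, sampleFrac)
    x <- dropFailedProbes(x, probePThreshold, probeFrac)
    x <- dropSexChromosomes(x)
    m <- betaToM(betaValues(x))
    if (quantile) {
        m <- quantileNormalize(m)
        x <- record_step(x, "quantileNormalize")
    }
    if (peak) {
        m <- peakCorrect(m, SummarizedExperiment::rowRanges(x)$designType)
        x <- record_step(x, "peakCorrect")
    }
    SummarizedExperiment::assay(x, "M", withDimnames = FALSE) <- m
    x
}
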