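#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom stats pt pchisq pnorm qnorm p.adjust uniroot density rnorm runif setNames
#' @importFrom utils read.csv read.delim write.table
NULL

#' Summary statistics of a control group
#'
#' Holds the mean, sample standard deviation (n - 1 denominator) and size of
#' the control scores against which a single case is tested. All single-case
#' statistics in this package are functions of these three numbers only, so a
#' `ControlSummary` can be built either from raw scores or directly from
#' published summary statistics.
#'
#' @slot mean numeric(1), control mean.
#' @slot sd numeric(1), control sample standard deviation (n - 1 denominator).
#' @slot n integer(1), number of controls (>= 2).
#'
#' @seealso [controlSummary()], [chTTest()], [effectSizeInterval()]
#' @export
setClass("ControlSummary",
    representation(mean = "numeric", sd = "numeric", n = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@mean) != 1L || !is.finite(object@mean))
            msg <- c(msg, "'mean' must be a single finite number")
        if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd < 0)
            msg <- c(msg, "'sd' must be a single finite non-negative number")
        if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
            msg <- c(msg, "'n' must be a single integer >= 2")
        if (is.null(msg)) TRUE else msg
    })

#' Result of a single-case t-test at one probe
#'
#' @slot method character(1), one of `"CH"` (Crawford-Howell), `"OS"`
#'   (one-sample) or `"WB"` (Weisberg outlier test).
#' @slot statistic numeric(1), the t statistic.
#' @slot df integer(1), degrees of freedom (n - 1 for CH and OS, n - 2 for WB).
#' @slot pLower numeric(1), lower-tail probability P(T_df <= statistic).
#' @slot pUpper numeric(1), upper-tail probability.
#' @slot pTwoSided numeric(1), 2 * min(pLower, pUpper).
#' @slot n integer(1), number of controls used.
#'
#' @seealso [chTTest()], [osTTest()], [wbTTest()]
#' @export
setClass("SingleCaseTest",
    representation(method = "character", statistic = "numeric",
                   df = "integer", pLower = "numeric", pUpper = "numeric",
                   pTwoSided = "numeric", n = "integer"),
    validity = function(object) {
        msg <- NULL
        if (!object@method %in% c("CH", "OS", "WB"))
            msg <- c(msg, "'method' must be one of CH, OS, WB")
        p <- c(object@pLower, object@pUpper, object@pTwoSided)
        if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
            msg <- c(msg, "tail probabilities must lie in [0, 1]")
        if (abs(object@pLower + object@pUpper - 1) > 1e-12)
            msg <- c(msg, "pLower + pUpper must equal 1")
        if (is.null(msg)) TRUE else msg
    })

#' Case-control effect size with noncentral-t confidence interval
#'
#' The effect size z_cc = (case - control mean) / control sd, its confidence
#' interval obtained by root-finding on the noncentral t CDF, and the
#' abnormality estimate: the percentage of the control population expected to
#' score below the case, with the interval carried to the percentage scale
#' through the standard normal CDF.
#'
#' @slot zcc numeric(1), effect-size point estimate.
#' @slot ciLower,ciUpper numeric(1), interval limits on the z scale.
#' @slot deltaLower,deltaUpper numeric(1), the underlying noncentrality
#'   parameters (interval limits times sqrt(n)).
#' @slot pctPoint numeric(1), abnormality point estimate in percent
#'   (100 times the lower-tail Crawford-Howell probability).
#' @slot pctLower,pctUpper numeric(1), percentage-scale interval.
#' @slot confidence numeric(1), confidence level in (0, 1).
#' @slot n integer(1), number of controls.
#'
#' @seealso [effectSizeInterval()]
#' @export
setClass("EffectSizeEstimate",
    representation(zcc = "numeric", ciLower = "numeric", ciUpper = "numeric",
                   deltaLower = "numeric", deltaUpper = "numeric",
                   pctPoint = "numeric", pctLower = "numeric",
                   pctUpper = "numeric", confidence = "numeric",
                   n = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@ciLower > object@zcc + 1e-8 ||
            object@zcc > object@ciUpper + 1e-8)
            msg <- c(msg, "zcc must lie inside [ciLower, ciUpper]")
        if (object@pctLower > object@pctUpper + 1e-9)
            msg <- c(msg, "pctLower must not exceed pctUpper")
        if (object@confidence <= 0 || object@confidence >= 1)
            msg <- c(msg, "'confidence' must be in (0, 1)")
        if (is.null(msg)) TRUE else msg
    })

#' Container for a single-case methylation array experiment
#'
#' Extends `RangedSummarizedExperiment` with two mandatory assays, `beta`
#' (methylation proportions in \[0, 1\], `NA` allowed) and `detectionP`
#' (per-probe per-sample detection p-values), probe annotation on the row
#' ranges (`probeID`, `designType`) and a `role` column in `colData` marking
#' exactly one sample as `"case"` and the others as `"control"`. Preprocessing
#' adds an `M` assay of normalised M values and records every filtering step
#' in `metadata(x)$preprocessing`.
#'
#' @seealso [MethylationExperiment()], [preprocess()], [testProbes()]
#' @export
setClass("MethylationExperiment",
    contains = "RangedSummarizedExperiment",
    validity = function(object) {
        msg <- NULL
        an <- SummarizedExperiment::assayNames(object)
        if (!all(c("beta", "detectionP") %in% an))
            return("assays 'beta' and 'detectionP' are required")
        b <- SummarizedExperiment::assay(object, "beta")
        if (any(b < 0 | b > 1, na.rm = TRUE))
            msg <- c(msg, "'beta' values must lie in [0, 1]")
        dp <- SummarizedExperiment::assay(object, "detectionP")
        if (any(dp < 0 | dp > 1, na.rm = TRUE))
            msg <- c(msg, "'detectionP' values must lie in [0, 1]")
        rd <- SummarizedExperiment::rowData(object)
        if (!all(c("probeID", "designType") %in% colnames(rd))) {
            msg <- c(msg, "rowData must contain 'probeID' and 'designType'")
        } else {
            if (anyDuplicated(rd$probeID))
                msg <- c(msg, "duplicate probe ids in manifest")
            if (!all(rd$designType %in% c("I", "II")))
                msg <- c(msg, "designType must be 'I' or 'II'")
        }
        cd <- SummarizedExperiment::colData(object)
        if (!"role" %in% colnames(cd)) {
            msg <- c(msg, "colData must contain a 'role' column")
        } else {
            if (!all(cd$role %in% c("case", "control")))
                msg <- c(msg, "roles must be 'case' or 'control'")
            if (sum(cd$role == "case") != 1L)
                msg <- c(msg, "exactly one sample must have role 'case'")
        }
        if (is.null(msg)) TRUE else msg
    })
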