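#' Summarise a control group
#'
#' Either pass a vector of control `scores`, or the summary statistics
#' directly (`mean`, `sd`, `n`) when only published summaries are available.
#' The standard deviation always uses the n - 1 denominator.
#'
#' @param scores numeric vector of control scores (`NA` dropped).
#' @param mean,sd,n summary statistics, used when `scores` is missing.
#' @return A [ControlSummary-class] object.
#' @examples
#' controlSummary(mean = 0.5, sd = 0.1, n = 10)
#' controlSummary(rnorm(20))
#' @export
controlSummary <- function(scores = NULL, mean = NULL, sd = NULL, n = NULL) {
    if (!is.null(scores)) {
        scores <- scores[!is.na(scores)]
        if (length(scores) < 2L)
            stop("need at least 2 non-missing control scores")
        new("ControlSummary", mean = base::mean(scores),
            sd = stats::sd(scores), n = length(scores))
    } else {
        if (is.null(mean) || is.null(sd) || is.null(n))
            stop("provide either 'scores' or all of 'mean', 'sd', 'n'")
        new("ControlSummary", mean = as.numeric(mean), sd = as.numeric(sd),
            n = as.integer(n))
    }
}

as_control_summary <- function(controls) {
    if (is(controls, "ControlSummary")) controls else controlSummary(controls)
}

## statistic + df for one method; the scale factor on s is what
## distinguishes the three tests
single_case_statistic <- function(case, ctl, method) {
    if (!is.finite(case)) stop("case score must be finite")
    if (method == "WB" && ctl@n < 3L)
        stop("insufficient controls: the Weisberg test needs n >= 3 (df = n - 2)")
    if (ctl@sd == 0) {
        if (case == ctl@mean) {
            stat <- 0
        } else {
            stop("degenerate controls: sd = 0 with case != control mean ",
                 "(statistic infinite)")
        }
    } else {
        stat <- switch(method,
            CH = (case - ctl@mean) / (ctl@sd * sqrt((ctl@n + 1) / ctl@n)),
            OS = (ctl@mean - case) / (ctl@sd / sqrt(ctl@n)),
            WB = (case - ctl@mean) / (ctl@sd * sqrt(ctl@n / (ctl@n - 1))))
    }
    df <- if (method == "WB") ctl@n - 2L else ctl@n - 1L
    list(statistic = stat, df = df)
}

single_case_test <- function(case, controls, method) {
    ctl <- as_control_summary(controls)
    sdf <- single_case_statistic(case, ctl, method)
    pl <- pt(sdf$statistic, df = sdf$df)
    new("SingleCaseTest", method = method, statistic = sdf$statistic,
        df = as.integer(sdf$df), pLower = pl, pUpper = 1 - pl,
        pTwoSided = 2 * min(pl, 1 - pl), n = ctl@n)
}

#' Single-case t-tests against a small control group
#'
#' Compare one case score with a group of n controls summarised by their mean
#' and sample standard deviation. Three tests are provided:
#'
#' * `chTTest()` — the Crawford-Howell test, which treats the control mean and
#'   SD as sample statistics rather than population parameters:
#'   t = (x* - xbar) / (s * sqrt((n + 1) / n)) on n - 1 df. This is the
#'   default test of the pipeline: it holds the type I error rate close to
#'   nominal even for very small control groups.
#' * `osTTest()` — the one-sample t-test with the case treated as the
#'   hypothesised population mean: t = (xbar - x*) / (s / sqrt(n)) on n - 1
#'   df. Note the reversed sign convention. Anti-conservative for this
#'   design (its type I error is well above nominal at small n); included for
#'   comparison.
#' * `wbTTest()` — the Weisberg outlier test:
#'   t = (x* - xbar) / (s * sqrt(n / (n - 1))) on n - 2 df. Slightly more
#'   conservative than Crawford-Howell.
#'
#' Lower, upper and two-sided tail probabilities from the central Student t
#' distribution are all reported; hypomethylation screening uses the lower
#' tail of the CH statistic.
#'
#' @param case numeric(1), the case score (typically an M value).
#' @param controls a [ControlSummary-class], or a numeric vector of control
#'   scores.
#' @return A [SingleCaseTest-class] object.
#' @examples
#' ctl <- controlSummary(mean = 0.5, sd = 0.1, n = 10)
#' chTTest(0.4, ctl)
#' osTTest(0.4, ctl)
#' wbTTest(0.4, ctl)
#' @export
chTTest <- function(case, controls) single_case_test(case, controls, "CH")

#' @rdname chTTest
#' @export
osTTest <- function(case, controls) single_case_test(case, controls, "OS")

#' @rdname chTTest
#' @export
wbTTest <- function(case, controls) single_case_test(case, controls, "WB")

#' @rdname SingleCaseTest-class
#' @export
setMethod("tStatistic", "SingleCaseTest", function(x) x@statistic)

#' @rdname SingleCaseTest-class
#' @export
setMethod("degreesOfFreedom", "SingleCaseTest", function(x) x@df)

#' @rdname SingleCaseTest-class
#' @export
setMethod("pValue", "SingleCaseTest",
    function(x, tail = c("lower", "upper", "two.sided")) {
        switch(match.arg(tail),
               lower = x@pLower, upper = x@pUpper, two.sided = x@pTwoSided)
    })

#' @rdname SingleCaseTest-class
#' @param object a `SingleCaseTest`.
#' @export
setMethod("show", "SingleCaseTest", function(object) {
    lab <- c(CH = "Crawford-Howell", OS = "one-sample",
             WB = "Weisberg")[object@method]
    cat(lab, "single-case t-test (", object@n, "controls )\n")
    cat(sprintf("  t = %.4f on %d df\n", object@statistic, object@df))
    cat(sprintf("  P(lower) = %.4g  P(upper) = %.4g  two-sided = %.4g\n",
                object@pLower, object@pUpper, object@pTwoSided))
    invisible(NULL)
})

#' Case-control effect size
#'
#' The standardised difference between the case score and the control mean,
#' z_cc = (x - xbar) / s. Analogous to Cohen's d for the single-case design.
#'
#' @inheritParams chTTest
#' @return numeric(1), the effect size.
#' @examples
#' effectSize(0.4, controlSummary(mean = 0.5, sd = 0.1, n = 10))  # -1
#' @export
effectSize <- function(case, controls) {
    ctl <- as_control_summary(controls)
    if (ctl@sd == 0)
        stop("degenerate controls: sd = 0, effect size undefined")
    (case - ctl@mean) / ctl@sd
}

## Solve pt(w, df, ncp = delta) == prob for delta. The CDF is strictly
## decreasing in delta, so a sign change brackets the unique root; the
## bracket starts at [w - 10, w + 10] and doubles until it straddles.
ncp_root <- function(w, df, prob, tol = 1e-8) {
    ## precision warnings from the noncentral CDF at extreme ncp are benign
    ## here: bisection keeps a guaranteed bracket either way
    f <- function(d) suppressWarnings(pt(w, df = df, ncp = d)) - prob
    half <- 10
    lo <- w - half
    hi <- w + half
    for (i in 1:60) {
        flo <- f(lo)
        fhi <- f(hi)
        if (is.finite(flo) && is.finite(fhi) && flo >= 0 && fhi <= 0) break
        half <- half * 2
        lo <- w - half
        hi <- w + half
        if (i == 60)
            stop("noncentrality root-finding failed to bracket: w = ", w,
                 ", df = ", df, ", prob = ", prob)
    }
    ## f decreasing: f(lo) >= 0 >= f(hi); plain bisection is robust to the
    ## limited accuracy of the noncentral CDF and gives a guaranteed bracket
    target <- tol * max(1, abs(w))
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (!is.finite(fm))
            stop("noncentral t CDF not finite at delta = ", mid,
                 " (w = ", w, ", df = ", df, ", prob = ", prob, ")")
        if (fm >= 0) lo <- mid else hi <- mid
        if (hi - lo < target) break
    }
    if (hi - lo >= max(target, 1e-6))
        stop("noncentrality root-finding did not converge: bracket [",
             lo, ", ", hi, "] for w = ", w, ", df = ", df,
             ", prob = ", prob)
    (lo + hi) / 2
}

#' Effect size with a noncentral-t confidence interval
#'
#' Computes z_cc and its confidence interval by the noncentral-t construction:
#' with w = z_cc * sqrt(n), the lower limit is the noncentrality parameter
#' delta_L for which the noncentral t distribution on n - 1 df has w as its
#' (1 + confidence)/2 quantile, divided by sqrt(n); the upper limit uses the
#' (1 - confidence)/2 quantile. The abnormality point estimate — the
#' percentage of the control population expected to score below the case — is
#' 100 times the lower-tail Crawford-Howell probability, and the interval
#' limits are carried to the percentage scale through the standard normal CDF
#' applied to the z-scale limits.
#'
#' @inheritParams chTTest
#' @param confidence confidence level, default 0.95.
#' @return An [EffectSizeEstimate-class] object.
#' @examples
#' es <- effectSizeInterval(0.4, controlSummary(mean = 0.5, sd = 0.1, n = 10))
#' es  # z_cc = -1, 95% CI (-1.751, -0.214)
#' @export
effectSizeInterval <- function(case, controls, confidence = 0.95) {
    ctl <- as_control_summary(controls)
    if (confidence <= 0 || confidence >= 1)
        stop("'confidence' must be in (0, 1)")
    zcc <- effectSize(case, ctl)
    w <- zcc * sqrt(ctl@n)
    df <- ctl@n - 1L
    dL <- ncp_root(w, df, (1 + confidence) / 2)
    dU <- ncp_root(w, df, (1 - confidence) / 2)
    ciL <- dL / sqrt(ctl@n)
    ciU <- dU / sqrt(ctl@n)
    pct <- 100 * pValue(chTTest(case, ctl), "lower")
    new("EffectSizeEstimate", zcc = zcc, ciLower = ciL, ciUpper = ciU,
        deltaLower = dL, deltaUpper = dU, pctPoint = pct,
        pctLower = 100 * pnorm(ciL), pctUpper = 100 * pnorm(ciU),
        confidence = confidence, n = ctl@n)
}

#' @rdname EffectSizeEstimate-class
#' @param object an `EffectSizeEstimate`.
#' @export
setMethod("show", "EffectSizeEstimate", function(object) {
    cat(sprintf("effect size z_cc = %.3f, %d%% CI (%.3f, %.3f), n = %d\n",
                object@zcc, round(100 * object@confidence),
                object@ciLower, object@ciUpper, object@n))
    cat(sprintf("abnormality: %.2f%% of controls expected below the case, CI (%.2f%%, %.2f%%)\n",
                object@pctPoint, object@pctLower, object@pctUpper))
    invisible(NULL)
})

#' Apply a single-case test across a matrix of probes
#'
#' Vectorised application of one single-case test to every row of a control
#' matrix, with per-row handling of missing control values: `NA` controls are
#' dropped and the effective n recorded. Rows with fewer than `minControls`
#' usable controls, or with zero control variance and a discrepant case, are
#' flagged `untestable` rather than dropped, so output rows stay aligned with
#' the input.
#'
#' @param caseScores numeric vector, one case score per probe.
#' @param controlMatrix numeric matrix, probes x controls, `NA` allowed.
#' @param method `"CH"`, `"OS"` or `"WB"`.
#' @param minControls minimum usable controls per row (default 2; the
#'   Weisberg test needs at least 3).
#' @return A data.frame with columns `statistic`, `df`, `pLower`, `pUpper`,
#'   `pTwoSided`, `effectiveN`, `untestable`.
#' @export
batchSingleCase <- function(caseScores, controlMatrix,
                            method = c("CH", "OS", "WB"), minControls = 2L) {
    method <- match.arg(method)
    controlMatrix <- as.matrix(controlMatrix)
    if (length(caseScores) != nrow(controlMatrix))
        stop("length(caseScores) must equal nrow(controlMatrix)")
    minControls <- max(as.integer(minControls), if (method == "WB") 3L else 2L)
    n <- rowSums(!is.na(controlMatrix))
    mu <- rowMeans(controlMatrix, na.rm = TRUE)
    ## row-wise sample SD without apply(): sum((x - mu)^2) / (n - 1)
    ss <- rowSums((controlMatrix - mu)^2, na.rm = TRUE)
    s <- sqrt(ss / pmax(n - 1, 1))
    scale <- switch(method,
        CH = s * sqrt((n + 1) / n),
        OS = s / sqrt(n),
        WB = s * sqrt(n / pmax(n - 1, 1)))
    num <- if (method == "OS") mu - caseScores else caseScores - mu
    stat <- num / scale
    stat[s == 0 & caseScores == mu] <- 0
    df <- as.integer(if (method == "WB") n - 2L else n - 1L)
    untestable <- n < minControls | (s == 0 & caseScores != mu) |
        !is.finite(caseScores)
    stat[untestable] <- NA_real_
    pl <- pt(stat, df = pmax(df, 1L))
    data.frame(statistic = stat, df = df, pLower = pl, pUpper = 1 - pl,
               pTwoSided = 2 * pmin(pl, 1 - pl), effectiveN = as.integer(n),
               untestable = untestable)
}
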