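#' Region-calling filter configuration
#'
#' Bundles the thresholds of the DMR screen. The defaults implement the
#' single-sample criteria: per-CpG one-tailed P < 0.05 with no multiple-testing
#' adjustment, control hemimethylation (mean control M in \[-1, +1\]),
#' hypomethylation only (case beta below control mean beta), and at least
#' three consecutive CpGs with adjacent members no more than 2000 nucleotides
#' apart. The `stringent` mode instead applies the cohort-style criterion:
#' BH-FDR-adjusted one-tailed P below `stringentFdrThreshold` (default 1e-7).
#'
#' @param pThreshold per-CpG one-tailed P threshold (default 0.05).
#' @param stringent logical; use the FDR-adjusted stringent criterion.
#' @param stringentFdrThreshold adjusted-P threshold in stringent mode.
#' @param controlMLow,controlMHigh hemimethylation band for the control mean
#'   M value (default -1 .. +1).
#' @param minProbes minimum CpGs per region (default 3).
#' @param maxGapNt maximum nucleotide gap (default 2000).
#' @param requireHypomethylation keep only probes with negative beta
#'   difference (case minus control); set `direction = "hyper"` to screen the
#'   other tail instead.
#' @param direction `"hypo"` (default) or `"hyper"`.
#' @param consecutiveScope `"hemimethylated"` (default): a run of candidates
#'   is broken by an intervening retained hemimethylated probe that is not
#'   itself a candidate; `"all"`: any retained probe breaks a run.
#' @param gapSemantics `"adjacent"` (default): the 2000-nt bound applies to
#'   each adjacent pair of member CpGs; `"span"`: it bounds the whole region
#'   span.
#' @return A list of class `FilterConfig`.
#' @export
filterConfig <- function(pThreshold = 0.05, stringent = FALSE,
                         stringentFdrThreshold = 1e-7,
                         controlMLow = -1, controlMHigh = 1,
                         minProbes = 3L, maxGapNt = 2000L,
                         requireHypomethylation = TRUE,
                         direction = c("hypo", "hyper"),
                         consecutiveScope = c("hemimethylated", "all"),
                         gapSemantics = c("adjacent", "span")) {
    stopifnot(minProbes >= 2L, maxGapNt > 0)
    structure(list(pThreshold = pThreshold, stringent = stringent,
                   stringentFdrThreshold = stringentFdrThreshold,
                   controlMLow = controlMLow, controlMHigh = controlMHigh,
                   minProbes = as.integer(minProbes),
                   maxGapNt = as.integer(maxGapNt),
                   requireHypomethylation = requireHypomethylation,
                   direction = match.arg(direction),
                   consecutiveScope = match.arg(consecutiveScope),
                   gapSemantics = match.arg(gapSemantics)),
              class = "FilterConfig")
}

#' Per-probe single-case tests on a pre-processed dataset
#'
#' Applies the chosen single-case t-test to every retained probe, testing the
#' case M value against the batch-matched controls. Missing control values
#' are dropped per probe (the effective n is recorded); probes with fewer
#' than `minControls` usable controls or degenerate control variance are
#' flagged untestable rather than dropped. Beta-scale differences are
#' recovered from the normalised M values via the inverse logit, so the
#' hypomethylation direction filter operates on the same normalised scale as
#' the test.
#'
#' @param x a pre-processed [MethylationExperiment-class] (with an `M` assay).
#' @param method `"CH"`, `"OS"` or `"WB"`.
#' @param minControls minimum usable controls per probe.
#' @return A data.frame with one row per retained probe: `probe_id`, `chrom`,
#'   `pos`, `t`, `df`, `pOneTailed` (the case-below-controls tail: lower for
#'   CH/WB, upper for the sign-reversed OS), `deltaM`, `deltaBeta`,
#'   `controlMeanM`, `effectiveN`, `untestable`.
#' @export
testProbes <- function(x, method = c("CH", "OS", "WB"), minControls = 2L) {
    method <- match.arg(method)
    m <- mValues(x)
    caseM <- m[, caseSample(x)]
    ctlM <- m[, controlSamples(x), drop = FALSE]
    if (ncol(ctlM) < 2L)
        stop("need at least 2 controls after QC")
    res <- batchSingleCase(caseM, ctlM, method = method,
                           minControls = minControls)
    ## the OS statistic has a reversed sign convention, so its
    ## case-below-controls tail is the upper one
    pHypo <- if (method == "OS") res$pUpper else res$pLower
    ctlMean <- rowMeans(ctlM, na.rm = TRUE)
    ctlBetaMean <- rowMeans(mToBeta(ctlM), na.rm = TRUE)
    mf <- probeManifest(x)
    data.frame(probe_id = mf$probe_id, chrom = mf$chrom, pos = mf$pos,
               t = res$statistic, df = res$df, pOneTailed = pHypo,
               deltaM = caseM - ctlMean,
               deltaBeta = mToBeta(caseM) - ctlBetaMean,
               controlMeanM = ctlMean, effectiveN = res$effectiveN,
               untestable = res$untestable, row.names = NULL)
}

#' Select candidate hypomethylated CpGs
#'
#' Retains probes that are hemimethylated in controls (mean control M inside
#' the configured band), individually significant (one-tailed P below the
#' threshold; BH-FDR-adjusted in stringent mode) and changed in the screened
#' direction (negative beta difference for hypomethylation). Untestable
#' probes never qualify.
#'
#' @param results data.frame from [testProbes()].
#' @param cfg a [filterConfig()].
#' @return The qualifying subset of `results`.
#' @export
filterCandidates <- function(results, cfg = filterConfig()) {
    p <- results$pOneTailed
    if (cfg$direction == "hyper")
        p <- 1 - p  # upper tail drives a hypermethylation screen
    sig <- if (cfg$stringent) {
        fdrAdjust(p) < cfg$stringentFdrThreshold
    } else {
        p < cfg$pThreshold
    }
    hemi <- results$controlMeanM >= cfg$controlMLow &
        results$controlMeanM <= cfg$controlMHigh
    dir <- if (!cfg$requireHypomethylation) TRUE
        else if (cfg$direction == "hypo") results$deltaBeta < 0
        else results$deltaBeta > 0
    keep <- !results$untestable & hemi & sig & dir
    keep[is.na(keep)] <- FALSE
    results[keep, , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; a thin wrapper over [stats::p.adjust()] kept as
#' the pipeline's single adjustment point.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length.
#' @export
fdrAdjust <- function(p) p.adjust(p, method = "BH")

#' Fisher's combined probability for one region
#'
#' X^2 = -2 * sum(ln p_i) referred to a chi-square distribution with 2k df.
#' The tail probability is computed in log space so that arbitrarily small
#' combined P values stay finite; `pDisplay` reports the value on the
#' probability scale, as 0 once it falls below 1e-350.
#'
#' @param p numeric vector of per-CpG p-values in (0, 1\]; zeros are replaced
#'   by the smallest representable positive double with a warning.
#' @return A list: `chi2`, `df` (= 2k), `log10P`, `pDisplay`.
#' @examples
#' fisherCombine(0.01)$pDisplay        # identity at k = 1
#' fisherCombine(c(0.05, 0.05))$chi2   # 11.98
#' @export
fisherCombine <- function(p) {
    if (length(p) == 0L)
        stop("no probes: Fisher combination needs at least one p-value")
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    if (any(p == 0)) {
        warning("zero p-value(s) replaced by the smallest positive double")
        p[p == 0] <- .Machine$double.xmin
    }
    chi2 <- -2 * sum(log(p))
    df <- 2L * length(p)
    log10P <- pchisq(chi2, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
    list(chi2 = chi2, df = df, log10P = log10P,
         pDisplay = if (log10P < -350) 0 else 10^log10P)
}

#' Assemble candidate CpGs into called regions
#'
#' A region is a maximal run of candidate probes that are consecutive in
#' genomic order among the retained probes in scope on that chromosome (by
#' default the hemimethylated ones, so an intervening retained hemimethylated
#' probe that failed the significance or direction filter breaks a run), with
#' every adjacent pair of members at most `maxGapNt` apart. Runs with at
#' least `minProbes` members are reported with 1-based inclusive coordinates
#' spanning their member positions and a Fisher-combined P over the member
#' p-values. Probes tied at one position are ordered by probe id, and the
#' result is invariant to input row order.
#'
#' @param candidates data.frame from [filterCandidates()].
#' @param allRetained data.frame from [testProbes()] — every probe that
#'   survived preprocessing, used to decide consecutiveness.
#' @param cfg a [filterConfig()].
#' @return A [GenomicRanges::GRanges] with metadata columns `k`, `probeIDs`
#'   (CharacterList), `fisherChi2`, `fisherDf`, `log10P`, `pDisplay`,
#'   `meanDeltaM`.
#' @export
callRegions <- function(candidates, allRetained, cfg = filterConfig()) {
    empty <- GenomicRanges::GRanges(
        k = integer(0), probeIDs = IRanges::CharacterList(),
        fisherChi2 = numeric(0), fisherDf = integer(0),
        log10P = numeric(0), pDisplay = numeric(0), meanDeltaM = numeric(0))
    if (nrow(candidates) == 0L) return(empty)

    scope <- if (cfg$consecutiveScope == "hemimethylated") {
        hemi <- allRetained$controlMeanM >= cfg$controlMLow &
            allRetained$controlMeanM <= cfg$controlMHigh
        allRetained[!is.na(hemi) & hemi, , drop = FALSE]
    } else {
        allRetained
    }
    ## candidates must appear in the scope set (they satisfy its filter)
    scope <- scope[order(scope$chrom, scope$pos, scope$probe_id), ,
                   drop = FALSE]
    isCand <- scope$probe_id %in% candidates$probe_id
    pLookup <- setNames(candidates$pOneTailed, candidates$probe_id)
    dmLookup <- setNames(candidates$deltaM, candidates$probe_id)

    runs <- list()
    cur <- integer(0)   # row indices into scope of the current run
    flush <- function(cur) {
        if (length(cur) >= cfg$minProbes) runs[[length(runs) + 1L]] <<- cur
    }
    for (i in seq_len(nrow(scope))) {
        if (!isCand[i]) {
            flush(cur); cur <- integer(0)
            next
        }
        if (length(cur)) {
            sameChrom <- scope$chrom[i] == scope$chrom[cur[1L]]
            gapOK <- if (cfg$gapSemantics == "adjacent") {
                scope$pos[i] - scope$pos[cur[length(cur)]] <= cfg$maxGapNt
            } else {
                scope$pos[i] - scope$pos[cur[1L]] <= cfg$maxGapNt
            }
            if (!sameChrom || !gapOK) {
                flush(cur); cur <- integer(0)
            }
        }
        cur <- c(cur, i)
    }
    flush(cur)
    if (!length(runs)) return(empty)

    ids <- lapply(runs, function(idx) scope$probe_id[idx])
    fc <- lapply(ids, function(i) fisherCombine(unname(pLookup[i])))
    gr <- GenomicRanges::GRanges(
        seqnames = vapply(runs, function(idx) scope$chrom[idx[1L]], ""),
        ranges = IRanges::IRanges(
            start = vapply(runs, function(idx) min(scope$pos[idx]), 0L),
            end = vapply(runs, function(idx) max(scope$pos[idx]), 0L)),
        k = lengths(runs), probeIDs = IRanges::CharacterList(ids),
        fisherChi2 = vapply(fc, `[[`, 0, "chi2"),
        fisherDf = vapply(fc, `[[`, 0L, "df"),
        log10P = vapply(fc, `[[`, 0, "log10P"),
        pDisplay = vapply(fc, `[[`, 0, "pDisplay"),
        meanDeltaM = vapply(ids, function(i) mean(unname(dmLookup[i])), 0))
    sort(gr, ignore.strand = TRUE)
}

#' Titrate control-group size
#'
#' Repeatedly subsamples the control pool without replacement at each
#' requested size, reruns the full test-filter-call pipeline on the same
#' case, and summarises the calls. When a truth set of injected DMR spans is
#' supplied (a data.frame with `chrom`, `start`, `end`), per-size sensitivity
#' is reported as the fraction of truth regions overlapped by a call, and
#' effect-size intervals are summarised at the truth probes. Deterministic
#' for a given seed.
#'
#' @param x a raw [MethylationExperiment-class] (preprocessing is rerun per
#'   subsample, as the normalisation depends on which controls are present).
#' @param sizes control-group sizes to assess (default 5, 10, 20, 30, 40,
#'   50); sizes above the available pool are skipped with a warning.
#' @param replicates subsamples per size.
#' @param method single-case test to use.
#' @param cfg a [filterConfig()].
#' @param truth optional data.frame of true DMR spans.
#' @param seed integer seed governing all subsampling.
#' @return A data.frame with one row per size x replicate: `size`,
#'   `replicate`, `nCandidates`, `nRegions`, and with truth: `sensitivity`,
#'   `meanZcc`, `meanCIWidth` over truth-region probes.
#' @export
controlTitration <- function(x, sizes = c(5, 10, 20, 30, 40, 50),
                             replicates = 1L, method = "CH",
                             cfg = filterConfig(), truth = NULL,
                             seed = 1L) {
    pool <- controlSamples(x)
    usable <- sizes[sizes <= length(pool)]
    if (length(usable) < length(sizes))
        warning("skipping size(s) above the control pool (",
                length(pool), "): ",
                paste(setdiff(sizes, usable), collapse = ", "))
    set.seed(seed)
    rows <- list()
    for (size in usable) {
        for (rep in seq_len(replicates)) {
            ctl <- sample(pool, size)
            sub <- x[, c(caseSample(x), ctl)]
            sub <- preprocess(sub)
            res <- testProbes(sub, method = method)
            cand <- filterCandidates(res, cfg)
            regions <- callRegions(cand, res, cfg)
            row <- data.frame(size = size, replicate = rep,
                              nCandidates = nrow(cand),
                              nRegions = length(regions))
            if (!is.null(truth)) {
                tg <- GenomicRanges::GRanges(
                    truth$chrom, IRanges::IRanges(truth$start, truth$end))
                row$sensitivity <- if (length(tg) == 0) NA_real_ else
                    mean(IRanges::overlapsAny(tg, regions))
                inTruth <- overlaps_positions(res$chrom, res$pos, truth)
                row <- cbind(row, truth_effect_summary(sub, res[inTruth, ]))
            }
            rows[[length(rows) + 1L]] <- row
        }
    }
    do.call(rbind, rows)
}

overlaps_positions <- function(chrom, pos, truth) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    s <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(truth$start, truth$end))
    IRanges::overlapsAny(q, s)
}

## mean z_cc and mean CI width across truth-region probes
truth_effect_summary <- function(x, res) {
    if (nrow(res) == 0L)
        return(data.frame(meanZcc = NA_real_, meanCIWidth = NA_real_))
    m <- mValues(x)[res$probe_id, , drop = FALSE]
    caseM <- m[, caseSample(x)]
    ctlM <- m[, controlSamples(x), drop = FALSE]
    ess <- lapply(seq_len(nrow(m)), function(i) {
        effectSizeInterval(caseM[i], controlSummary(ctlM[i, ]))
    })
    data.frame(
        meanZcc = mean(vapply(ess, slot, 0, "zcc")),
        meanCIWidth = mean(vapply(ess, function(e) e@ciUpper - e@ciLower, 0)))
}
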