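#' Specify an injected differentially methylated region
#'
#' Describes one imprinted-like DMR for the simulator: a span of
#' hemimethylated CpGs in controls (beta near `controlBetaMean`, M near 0)
#' at which the case loses methylation in a fraction `effect` of its cells.
#' `effect = 1` is complete loss of methylation (the behaviour of the
#' cardinal locus in transient neonatal diabetes); intermediate values model
#' the mosaic, attenuated hypomethylation typical of multi-locus methylation
#' disorders.
#'
#' @param chrom chromosome name.
#' @param start,end 1-based span within which the probes are placed.
#' @param nProbes number of CpG probes in the DMR.
#' @param controlBetaMean control methylation proportion (default 0.5,
#'   hemimethylation).
#' @param effect mosaic fraction of cells losing methylation, in \[0, 1\].
#' @param label name of the DMR in the truth set.
#' @return A list of class `DMRSpec`.
#' @export
dmrSpec <- function(chrom, start, end, nProbes, controlBetaMean = 0.5,
                    effect = 1, label = "dmr") {
    stopifnot(effect >= 0, effect <= 1, nProbes >= 1, end >= start)
    if (nProbes > end - start + 1)
        stop("DMR '", label, "': ", nProbes, " probes do not fit in a ",
             end - start + 1, "-nt span")
    structure(list(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), nProbes = as.integer(nProbes),
                   controlBetaMean = controlBetaMean, effect = effect,
                   label = label), class = "DMRSpec")
}

#' Configuration for the 450k-style simulator
#'
#' Defaults describe the study conditions the package targets: a single case
#' against 20 batch-matched controls (the control-group size found optimal
#' for this design), a bimodal background of mostly unmethylated /
#' methylated CpGs, about half type II probes whose M values are compressed
#' toward 0 by a factor of 2/3 (mimicking the reduced dynamic range that
#' peak correction undoes), sporadic missing betas and detection failures.
#'
#' @param nBackgroundProbes number of non-DMR probes.
#' @param nControls number of control samples.
#' @param dmrSpecs list of [dmrSpec()] objects.
#' @param betaNoiseSd per-sample noise SD on the M (logit) scale.
#' @param typeIIFraction fraction of probes assayed with Infinium II
#'   chemistry.
#' @param typeIIPeakShrink compression factor (< 1) applied to type II M
#'   values before back-transformation.
#' @param missingRate fraction of beta cells set missing.
#' @param detectionFailRate fraction of detection-p cells drawn from the
#'   failed-measurement regime.
#' @param seed integer seed; mandatory, every random draw flows from it.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nBackgroundProbes = 2000L, nControls = 20L,
                             dmrSpecs = list(), betaNoiseSd = 0.4,
                             typeIIFraction = 0.5, typeIIPeakShrink = 2 / 3,
                             missingRate = 0.001, detectionFailRate = 0.001,
                             seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    rates <- c(typeIIFraction, missingRate, detectionFailRate)
    stopifnot(all(rates >= 0 & rates <= 1), typeIIPeakShrink < 1,
              typeIIPeakShrink > 0, betaNoiseSd > 0, nControls >= 2)
    structure(list(nBackgroundProbes = as.integer(nBackgroundProbes),
                   nControls = as.integer(nControls), dmrSpecs = dmrSpecs,
                   betaNoiseSd = betaNoiseSd, typeIIFraction = typeIIFraction,
                   typeIIPeakShrink = typeIIPeakShrink,
                   missingRate = missingRate,
                   detectionFailRate = detectionFailRate,
                   seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a single-case methylation dataset with known truth
#'
#' Generates a probe manifest, beta matrix and detection-p matrix emulating
#' the features the pipeline must handle. Background probes follow a
#' two-component mixture centred near beta 0.1 and 0.9 (the unmethylated and
#' methylated peaks of a 450k array); DMR probes are hemimethylated in
#' controls (beta near `controlBetaMean`, M near 0, so they pass the
#' M-in-\[-1, 1\] imprinting filter by construction). The case's DMR betas
#' are linearly mixed toward 0 by the mosaic `effect`
#' (beta = controlBetaMean * (1 - effect)), matching the biology of a
#' cellular mosaic. Noise is added on the logit scale and back-transformed,
#' keeping betas in (0, 1) without truncation artefacts. Type II probes' M
#' values are compressed toward 0 by `typeIIPeakShrink` before conversion to
#' beta, creating the target that peak correction must undo. Missing betas
#' and failed detection p-values are injected independently at the
#' configured rates. Fully reproducible from the seed.
#'
#' @param cfg a [simulationConfig()].
#' @return A list: `dataset` (a [MethylationExperiment-class], case sample
#'   `"case01"`) and `truth` (data.frame with per-probe `probe_id`, `label`,
#'   `effect`).
#' @examples
#' cfg <- simulationConfig(nBackgroundProbes = 100, seed = 42,
#'     dmrSpecs = list(dmrSpec("chr6", 10000, 12000, 8, label = "imprintA")))
#' sim <- simulate450k(cfg)
#' table(sim$truth$label)
#' @export
simulate450k <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    nb <- cfg$nBackgroundProbes
    ## background manifest: probes spread over autosomes + a few sex-chrom
    ## probes so the sex filter always has work to do
    bgChrom <- sample(paste0("chr", c(1:22, "X", "Y")), nb, replace = TRUE,
                      prob = c(rep(0.96 / 22, 22), 0.02, 0.02))
    bgPos <- integer(nb)
    for (ch in unique(bgChrom)) {
        idx <- bgChrom == ch
        ## wide spacing so background probes rarely form spurious runs
        bgPos[idx] <- sort(sample.int(2e8, sum(idx)))
    }
    bg <- data.frame(probe_id = sprintf("cgB%06d", seq_len(nb)),
                     chrom = bgChrom, pos = bgPos,
                     label = "background", controlBetaMean = NA_real_,
                     effect = 0)
    dmr <- do.call(rbind, lapply(cfg$dmrSpecs, function(d) {
        pos <- sort(as.integer(round(seq(d$start, d$end,
                                         length.out = d$nProbes))))
        data.frame(probe_id = sprintf("cg%s%03d", d$label, seq_len(d$nProbes)),
                   chrom = d$chrom, pos = pos, label = d$label,
                   controlBetaMean = d$controlBetaMean, effect = d$effect)
    }))
    probes <- rbind(bg, dmr)
    probes <- probes[order(probes$chrom, probes$pos, probes$probe_id), ]
    nP <- nrow(probes)
    nS <- cfg$nControls + 1L
    samples <- c("case01", sprintf("ctrl%02d", seq_len(cfg$nControls)))

    isDMR <- probes$label != "background"
    ## per-probe baseline M: bimodal background, hemimethylated DMRs
    m0 <- numeric(nP)
    highPeak <- runif(sum(!isDMR)) < 0.5
    m0[!isDMR] <- rnorm(sum(!isDMR), mean = ifelse(highPeak, 3.17, -3.17),
                        sd = 0.5)
    if (any(isDMR))
        m0[isDMR] <- betaToM(probes$controlBetaMean[isDMR]) +
            rnorm(sum(isDMR), sd = 0.1)

    ## control M values: baseline + logit-scale noise
    m <- matrix(rep(m0, nS), nrow = nP, ncol = nS,
                dimnames = list(probes$probe_id, samples))
    ## case baseline at DMR probes: mosaic mixing on the beta scale
    if (any(isDMR)) {
        b0case <- mToBeta(m0[isDMR]) * (1 - probes$effect[isDMR])
        m[isDMR, 1L] <- betaToM(b0case)
    }
    m <- m + matrix(rnorm(nP * nS, sd = cfg$betaNoiseSd), nP, nS)

    designType <- ifelse(runif(nP) < cfg$typeIIFraction, "II", "I")
    m[designType == "II", ] <- m[designType == "II", ] * cfg$typeIIPeakShrink
    beta <- mToBeta(m)

    detP <- matrix(runif(nP * nS, 0, 1e-6), nP, nS,
                   dimnames = dimnames(beta))
    fail <- matrix(runif(nP * nS) < cfg$detectionFailRate, nP, nS)
    detP[fail] <- runif(sum(fail), 0.05, 1)
    beta[matrix(runif(nP * nS) < cfg$missingRate, nP, nS)] <- NA_real_

    manifest <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                           pos = probes$pos, design_type = designType)
    ds <- MethylationExperiment(manifest, beta, detP, case = "case01")
    truth <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                        pos = probes$pos, label = probes$label,
                        effect = probes$effect)
    list(dataset = ds, truth = truth)
}

#' Truth DMR spans from a simulation
#'
#' Collapses the per-probe truth table to one row per injected DMR, giving
#' the span of its probes — the shape [controlTitration()] and overlap
#' checks expect.
#'
#' @param truth the `truth` data.frame from [simulate450k()].
#' @return data.frame with `label`, `chrom`, `start`, `end`, `nProbes`,
#'   `effect`.
#' @export
truthRegions <- function(truth) {
    t2 <- truth[truth$label != "background", , drop = FALSE]
    if (nrow(t2) == 0L)
        return(data.frame(label = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          nProbes = integer(0), effect = numeric(0)))
    out <- do.call(rbind, lapply(split(t2, t2$label), function(d) {
        data.frame(label = d$label[1L], chrom = d$chrom[1L],
                   start = min(d$pos), end = max(d$pos), nProbes = nrow(d),
                   effect = d$effect[1L])
    }))
    rownames(out) <- NULL
    out
}

#' Empirical type I error of the single-case tests
#'
#' Draws `nReps` null replicates — a case and `nControls` controls from one
#' normal distribution — and scores each with the requested tests on the
#' same draws (paired across methods), returning the fraction of replicates
#' with lower-tail p below `alpha`. The Crawford-Howell rate sits at the
#' nominal level; the one-sample test is materially inflated at small n.
#'
#' @param nReps number of null replicates (>= 1000 for stable estimates).
#' @param nControls controls per replicate.
#' @param method character vector of tests to score.
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return Named numeric vector of empirical rejection rates.
#' @export
type1ErrorExperiment <- function(nReps = 20000L, nControls = 20L,
                                 method = c("CH", "OS", "WB"), alpha = 0.05,
                                 seed = 1L) {
    set.seed(seed)
    ctl <- matrix(rnorm(nReps * nControls), nReps, nControls)
    case <- rnorm(nReps)
    vapply(method, function(mth) {
        res <- batchSingleCase(case, ctl, method = mth)
        mean(res$pLower < alpha)
    }, 0)
}

#' Biological-replicate stability of the pipeline
#'
#' Splits a simulated control pool into two disjoint groups, runs the full
#' pipeline on the same case against each, and reports the per-run candidate
#' CpG sets and called regions with their overlap — the synthetic analogue of
#' processing one patient with two independent batch-matched control groups.
#'
#' @param cfg a [simulationConfig()] whose `nControls` supplies the pool;
#'   must be at least `2 * groupSize`.
#' @param groupSize controls per group (default 20).
#' @param method single-case test.
#' @param filter a [filterConfig()].
#' @return A list: `nCandidates1`, `nCandidates2`, `intersectionSize`,
#'   `jaccard` over candidate probe ids; `regions1`, `regions2` (GRanges);
#'   `regionOverlap` — fraction of run-1 regions overlapped by run 2.
#' @export
replicateOverlapExperiment <- function(cfg, groupSize = 20L, method = "CH",
                                       filter = filterConfig()) {
    if (cfg$nControls < 2L * groupSize)
        stop("control pool (", cfg$nControls, ") too small for two disjoint ",
             "groups of ", groupSize)
    sim <- simulate450k(cfg)
    pool <- controlSamples(sim$dataset)
    g1 <- pool[seq_len(groupSize)]
    g2 <- pool[groupSize + seq_len(groupSize)]
    runOne <- function(grp) {
        sub <- sim$dataset[, c(caseSample(sim$dataset), grp)]
        sub <- preprocess(sub)
        res <- testProbes(sub, method = method)
        cand <- filterCandidates(res, filter)
        list(cand = cand, regions = callRegions(cand, res, filter))
    }
    r1 <- runOne(g1)
    r2 <- runOne(g2)
    common <- intersect(r1$cand$probe_id, r2$cand$probe_id)
    uni <- union(r1$cand$probe_id, r2$cand$probe_id)
    list(nCandidates1 = nrow(r1$cand), nCandidates2 = nrow(r2$cand),
         intersectionSize = length(common),
         jaccard = if (length(uni)) length(common) / length(uni) else NA_real_,
         regions1 = r1$regions, regions2 = r2$regions,
         regionOverlap = if (length(r1$regions))
             mean(IRanges::overlapsAny(r1$regions, r2$regions)) else NA_real_,
         truth = truthRegions(sim$truth))
}
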