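# Fixtures are built in code: small manifests/matrices, an experiment whose
# M assay is set directly (bypassing normalisation) so probe-level tests can
# use exact control summaries, and an independent O(n^2) region-caller
# oracle.

makeManifest <- function(n, chrom = "chr1", pos = NULL, design = "II") {
    data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
               chrom = rep(chrom, length.out = n),
               pos = if (is.null(pos)) seq_len(n) * 10000L else pos,
               design_type = rep(design, length.out = n))
}

makeDataset <- function(beta, detP = NULL, manifest = NULL,
                        case = colnames(beta)[1L]) {
    if (is.null(colnames(beta)))
        colnames(beta) <- c("case01",
                            sprintf("ctrl%02d", seq_len(ncol(beta) - 1L)))
    if (is.null(detP))
        detP <- matrix(1e-8, nrow(beta), ncol(beta))
    dimnames(detP) <- dimnames(beta)
    if (is.null(manifest)) manifest <- makeManifest(nrow(beta))
    rownames(beta) <- rownames(detP) <- manifest$probe_id
    MethylationExperiment(manifest, beta, detP, case = colnames(beta)[1L])
}

## experiment with a prescribed M assay (normalisation skipped)
makeMExperiment <- function(m, manifest = NULL) {
    if (is.null(colnames(m)))
        colnames(m) <- c("case01",
                         sprintf("ctrl%02d", seq_len(ncol(m) - 1L)))
    x <- makeDataset(mToBeta(m), manifest = manifest)
    SummarizedExperiment::assay(x, "M", withDimnames = FALSE) <- m
    x
}

## a control vector with exact mean mu and sample sd s
exactControls <- function(n, mu, s, seed = 1) {
    set.seed(seed)
    v <- rnorm(n)
    v <- (v - mean(v)) / sd(v)
    mu + s * v
}

## Independent O(n^2) implementation of the region rule: enumerate every
## window of scope-consecutive probes, keep windows that are all-candidate
## with adjacent gaps <= maxGap, then keep the maximal ones.
bruteForceRegions <- function(scope, minProbes = 3L, maxGap = 2000L) {
    scope <- scope[order(scope$chrom, scope$pos, scope$probe_id), ,
                   drop = FALSE]
    nOK <- nrow(scope)
    valid <- list()
    for (i in seq_len(nOK)) {
        for (j in i:nOK) {
            idx <- i:j
            if (any(!scope$candidate[idx])) next
            if (length(unique(scope$chrom[idx])) != 1L) next
            if (length(idx) > 1L &&
                any(diff(scope$pos[idx]) > maxGap)) next
            valid[[length(valid) + 1L]] <- idx
        }
    }
    isMaximal <- vapply(valid, function(a) {
        !any(vapply(valid, function(b)
            length(b) > length(a) && all(a %in% b), TRUE))
    }, TRUE)
    keep <- valid[isMaximal]
    keep <- keep[vapply(keep, length, 0L) >= minProbes]
    if (!length(keep))
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), k = integer(0)))
    out <- do.call(rbind, lapply(keep, function(idx) {
        data.frame(chrom = scope$chrom[idx[1L]],
                   start = min(scope$pos[idx]), end = max(scope$pos[idx]),
                   k = length(idx))
    }))
    out[order(out$chrom, out$start), , drop = FALSE]
}

## random scope/candidate fixture for the oracle comparison
randomRegionFixture <- function(nProbes, seed) {
    set.seed(seed)
    chrom <- sort(sample(c("chr1", "chr2"), nProbes, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(nProbes), chrom), function(i)
        sort(sample.int(50000L, length(i)))), use.names = FALSE)
    data.frame(probe_id = sprintf("cg%05d", seq_len(nProbes)),
               chrom = chrom, pos = pos,
               t = rnorm(nProbes), df = 19L,
               pOneTailed = runif(nProbes),
               deltaM = rnorm(nProbes), deltaBeta = -abs(rnorm(nProbes)),
               controlMeanM = runif(nProbes, -0.5, 0.5),
               effectiveN = 20L, untestable = FALSE,
               candidate = runif(nProbes) < 0.5)
}

## standard simulation used by several end-to-end tests
simWithDMR <- function(effect = 1, nControls = 20L, seed = 101,
                       nBackground = 800L, nProbes = 10L) {
    simulate450k(simulationConfig(
        nBackgroundProbes = nBackground, nControls = nControls,
        dmrSpecs = list(dmrSpec("chr6", 144000000L, 144002000L, nProbes,
                                effect = effect, label = "dmr1")),
        seed = seed))
}
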