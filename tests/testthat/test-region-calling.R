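test_that("per-probe tests reproduce the scalar worked example and the null", {
    # one probe engineered to the published summary statistics
    ctl <- exactControls(10, 0.5, 0.1, seed = 5)
    m <- matrix(c(0.4, ctl), nrow = 1)
    m <- rbind(m, c(0, rnorm(10, 0, 0.2)))       # second probe, case at mean
    m[2, 1] <- mean(m[2, -1])
    me <- makeMExperiment(m)
    res <- testProbes(me, method = "CH")
    expect_equal(res$t[1], -1 / sqrt(1.1), tolerance = 1e-10)
    expect_equal(abs(round(res$t[1], 3)), 0.953, tolerance = 1e-9)
    expect_identical(res$df[1], 9L)
    expect_equal(res$pOneTailed[2], 0.5)
    expect_equal(res$deltaM[1], -0.1, tolerance = 1e-10)
    expect_lt(res$deltaBeta[1], 0)

    # 500-probe null: ~5% of probes significant at the 5% level
    set.seed(13)
    null <- matrix(rnorm(500 * 21, 0, 0.3), 500, 21)
    resNull <- testProbes(makeMExperiment(null))
    rate <- mean(resNull$pOneTailed < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("candidate filtering enforces hemimethylation, significance, direction", {
    res <- data.frame(
        probe_id = sprintf("cg%02d", 1:10),
        chrom = "chr1", pos = 1:10 * 1000L,
        t = -3, df = 19L,
        pOneTailed = c(1e-9, 0.2,  1e-3, 0.04, 1e-6, 0.9, 1e-4, 0.01, 0.049, 0.2),
        deltaM = -1, deltaBeta = c(-.1, -.1, +.2, -.1, -.1, -.1, -.1, -.1, -.1, -.1),
        controlMeanM = c(2.5, 0, 0, 0.5, -0.5, 0, -1.5, 0.99, -0.99, 0),
        effectiveN = 20L, untestable = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                                         FALSE, FALSE, FALSE, FALSE, FALSE))
    kept <- filterCandidates(res, filterConfig())
    # excluded: 1 fully methylated, 2/6/10 insignificant, 3 wrong direction,
    # 5 untestable, 7 outside the M band
    expect_identical(kept$probe_id, c("cg04", "cg08", "cg09"))

    # stringent mode: BH-adjusted P against 1e-7; cg01 is hemimethylated here
    res2 <- res[c(2, 3, 4), ]
    res2$pOneTailed <- c(1e-9, 1e-6, 0.5)
    res2$deltaBeta <- -0.1
    strict <- filterCandidates(res2, filterConfig(stringent = TRUE))
    expect_identical(strict$probe_id, "cg02")  # 1e-9 * 3 / 1 = 3e-9 < 1e-7
    # while 1e-6 adjusts to 1.5e-6, above the stringent threshold
})

test_that("regions need three consecutive close CpGs; gaps and intruders split runs", {
    mkres <- function(pos, p, chrom = "chr1", cmm = 0) {
        data.frame(probe_id = sprintf("cg%04d", seq_along(pos)),
                   chrom = chrom, pos = as.integer(pos), t = -3, df = 19L,
                   pOneTailed = p, deltaM = -1, deltaBeta = -0.1,
                   controlMeanM = rep(cmm, length.out = length(pos)),
                   effectiveN = 20L, untestable = FALSE)
    }
    cfg <- filterConfig()

    # two adjacent candidates only: below minProbes
    res <- mkres(c(100, 600), c(0.01, 0.01))
    expect_length(callRegions(filterCandidates(res, cfg), res, cfg), 0L)

    # 100/600/1100 within gaps; 9000/9400 pair fails minProbes
    res <- mkres(c(100, 600, 1100, 9000, 9400), rep(0.01, 5))
    reg <- callRegions(filterCandidates(res, cfg), res, cfg)
    expect_length(reg, 1L)
    expect_identical(GenomicRanges::start(reg), 100L)
    expect_identical(GenomicRanges::end(reg), 1100L)
    expect_identical(reg$k, 3L)
    expect_identical(reg$fisherDf, 6L)

    # an intervening retained hemimethylated non-candidate breaks the run
    res <- mkres(c(100, 600, 1100, 1600, 2100, 2600),
                 c(0.01, 0.01, 0.01, 0.5, 0.01, 0.01))
    reg <- callRegions(filterCandidates(res, cfg), res, cfg)
    expect_length(reg, 1L)          # 100-1100 survives; 2100/2600 too short
    expect_identical(GenomicRanges::end(reg), 1100L)

    # ... but a non-hemimethylated intruder does not (scope rule)
    res$controlMeanM <- c(0, 0, 0, 2.5, 0, 0)
    res$pOneTailed[4] <- 0.5
    reg <- callRegions(filterCandidates(res, cfg), res, cfg)
    # 1100 -> 2100 gap is 1000 <= 2000, so the run continues through
    expect_length(reg, 1L)
    expect_identical(reg$k, 5L)

    # under consecutiveScope = "all" the same intruder splits
    cfgAll <- filterConfig(consecutiveScope = "all")
    regAll <- callRegions(filterCandidates(res, cfgAll), res, cfgAll)
    expect_length(regAll, 1L)
    expect_identical(regAll$k, 3L)

    # row-order invariance and no leakage of non-candidates into members
    res <- mkres(c(100, 600, 1100, 9000, 9400, 9800), rep(0.01, 6))
    cand <- filterCandidates(res, cfg)
    shuffled <- res[c(4, 1, 6, 3, 2, 5), ]
    reg1 <- callRegions(cand, res, cfg)
    reg2 <- callRegions(filterCandidates(shuffled, cfg), shuffled, cfg)
    expect_equal(reg1, reg2)
    expect_true(all(unlist(reg1$probeIDs) %in% cand$probe_id))
})

test_that("region calls agree with the O(n^2) brute-force oracle", {
    cfg <- filterConfig(consecutiveScope = "all")
    for (seed in c(101, 202, 303, 404, 505)) {
        fx <- randomRegionFixture(sample(c(60, 120, 200), 1), seed = seed)
        fx$pOneTailed <- ifelse(fx$candidate, 0.01, 0.5)
        cand <- filterCandidates(fx, cfg)
        expect_identical(sort(cand$probe_id),
                         sort(fx$probe_id[fx$candidate]))
        reg <- callRegions(cand, fx, cfg)
        oracle <- bruteForceRegions(fx, minProbes = 3L, maxGap = 2000L)
        expect_identical(length(reg), nrow(oracle))
        if (length(reg)) {
            expect_identical(as.character(GenomicRanges::seqnames(reg)),
                             oracle$chrom)
            expect_identical(GenomicRanges::start(reg), oracle$start)
            expect_identical(GenomicRanges::end(reg), oracle$end)
            expect_identical(reg$k, oracle$k)
        }
    }
})

test_that("Fisher combination: identity at k=1, hand value at k=2, log-space tails", {
    one <- fisherCombine(0.01)
    expect_equal(one$pDisplay, 0.01, tolerance = 1e-12)
    expect_identical(one$df, 2L)

    two <- fisherCombine(c(0.05, 0.05))
    expect_equal(two$chi2, 11.9829, tolerance = 1e-4)
    expect_identical(two$df, 4L)
    expect_equal(two$pDisplay,
                 pchisq(-2 * log(0.05 * 0.05), 4, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_lt(abs(two$pDisplay - 0.0175), 1e-4)

    # underflow: displayed as 0 below 1e-350, log10 P stays finite
    tiny <- fisherCombine(rep(1e-12, 40))
    expect_identical(tiny$pDisplay, 0)
    expect_true(is.finite(tiny$log10P))
    expect_lt(tiny$log10P, -350)

    expect_warning(z <- fisherCombine(c(0, 0.5)), "zero")
    expect_true(is.finite(z$log10P))
    expect_error(fisherCombine(numeric(0)), "no probes")
})

test_that("BH adjustment matches the hand computation and is monotone", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(fdrAdjust(0.2), 0.2)
    expect_equal(fdrAdjust(rep(0.07, 5)), rep(0.07, 5))
    set.seed(17)
    p <- runif(50)
    adj <- fdrAdjust(p)
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("control titration is seeded, skips oversize groups, reports truth", {
    sim <- simWithDMR(effect = 1, nControls = 15L, seed = 55,
                      nBackground = 300L)
    truth <- truthRegions(sim$truth)
    expect_warning(
        rep1 <- controlTitration(sim$dataset, sizes = c(5, 10, 20),
                                 truth = truth, seed = 3),
        "skipping")
    expect_identical(sort(unique(rep1$size)), c(5, 10))
    expect_warning(
        rep2 <- controlTitration(sim$dataset, sizes = c(5, 10, 20),
                                 truth = truth, seed = 3),
        "skipping")
    expect_identical(rep1, rep2)   # same seed, identical report
    expect_true(all(c("sensitivity", "meanZcc", "meanCIWidth") %in%
                    colnames(rep1)))
})
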