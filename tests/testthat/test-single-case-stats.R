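ctl10 <- controlSummary(mean = 0.5, sd = 0.1, n = 10)

test_that("the three tests reproduce the published worked example", {
    ch <- chTTest(0.4, ctl10)
    os <- osTTest(0.4, ctl10)
    wb <- wbTTest(0.4, ctl10)

    # CH: t = -0.1 / (0.1 * sqrt(11/10)); 9 df
    expect_equal(tStatistic(ch), -1 / sqrt(1.1), tolerance = 1e-12)
    expect_identical(degreesOfFreedom(ch), 9L)
    # OS (reversed sign convention): t = sqrt(10); 9 df
    expect_equal(round(tStatistic(os), 3), 3.162)
    expect_identical(degreesOfFreedom(os), 9L)
    # WB: t = -sqrt(0.9); 8 df
    expect_equal(round(tStatistic(wb), 3), -0.949)
    expect_identical(degreesOfFreedom(wb), 8L)

    # the printed probabilities match the two-sided Student tails to 3 dp
    expect_lt(abs(pValue(ch, "two.sided") - 0.365), 1e-3)
    expect_lt(abs(pValue(os, "two.sided") - 0.012), 1e-3)
    expect_lt(abs(pValue(wb, "two.sided") - 0.371), 1e-3)
})

test_that("tail probabilities are coherent and match a quadrature oracle", {
    # independent oracle: numerical integration of the t density
    tDens <- function(x, df)
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
            (1 + x^2 / df)^(-(df + 1) / 2)
    stat <- -0.2 / (0.1 * sqrt(21 / 20))
    expect_equal(stat, -1.9518, tolerance = 1e-4)
    oracle <- integrate(tDens, -Inf, stat, df = 19)$value
    res <- chTTest(0.3, controlSummary(mean = 0.5, sd = 0.1, n = 20))
    expect_equal(pValue(res, "lower"), oracle, tolerance = 1e-6)

    # identity case
    id <- chTTest(0.5, ctl10)
    expect_identical(tStatistic(id), 0)
    expect_equal(pValue(id, "lower"), 0.5)

    set.seed(42)
    for (i in 1:20) {
        r <- chTTest(rnorm(1), controlSummary(rnorm(8)))
        expect_equal(pValue(r, "lower") + pValue(r, "upper"), 1)
        expect_equal(pValue(r, "two.sided"),
                     2 * min(pValue(r, "lower"), pValue(r, "upper")))
    }
})

test_that("algebraic identities link the three statistics on random inputs", {
    set.seed(7)
    for (i in 1:1000) {
        n <- sample(3:50, 1)
        ctl <- controlSummary(mean = rnorm(1), sd = rexp(1) + 0.01, n = n)
        x <- rnorm(1, ctl@mean, 2 * ctl@sd)
        tch <- tStatistic(chTTest(x, ctl))
        tos <- tStatistic(osTTest(x, ctl))
        twb <- tStatistic(wbTTest(x, ctl))
        expect_equal(tos, -tch * sqrt(n + 1), tolerance = 1e-10)
        expect_equal(twb, tch * sqrt(n^2 - 1) / n, tolerance = 1e-10)
        if (x != ctl@mean) {
            expect_lt(abs(twb), abs(tch))
            # hence the Weisberg test is (slightly) less significant
            expect_gte(pValue(wbTTest(x, ctl), "two.sided"),
                       pValue(chTTest(x, ctl), "two.sided"))
        }
    }
})

test_that("degenerate and insufficient control groups are signalled", {
    degenerate <- controlSummary(mean = 0.5, sd = 0, n = 10)
    expect_error(chTTest(0.4, degenerate), "degenerate")
    expect_error(effectSize(0.4, degenerate), "degenerate")
    expect_identical(tStatistic(chTTest(0.5, degenerate)), 0)
    expect_error(wbTTest(0.4, controlSummary(mean = 0.5, sd = 0.1, n = 2)),
                 "insufficient")
    expect_error(controlSummary(mean = 0.5, sd = 0.1, n = 1))
    expect_error(controlSummary(c(0.4, NA)), "at least 2")
})

test_that("controlSummary reproduces the mean and sd of raw scores", {
    set.seed(3)
    x <- rnorm(25, 2, 3)
    cs <- controlSummary(x)
    expect_equal(cs@mean, mean(x))
    expect_equal(cs@sd, sd(x))
    expect_identical(cs@n, 25L)
})

test_that("CH converges to the normal-curve method for large control groups", {
    ctl <- controlSummary(mean = 0, sd = 1, n = 1e5)
    for (z in c(-2.5, -1, 0.3, 1.7)) {
        expect_lt(abs(pValue(chTTest(z, ctl), "lower") - pnorm(z)), 1e-3)
    }
})

test_that("effect size and its noncentral-t interval match the worked example", {
    expect_equal(effectSize(0.4, ctl10), -1)
    expect_equal(effectSize(0.5, ctl10), 0)
    expect_equal(effectSize(0.7, ctl10), 2)

    es <- effectSizeInterval(0.4, ctl10, confidence = 0.95)
    expect_equal(es@zcc, -1)
    expect_lt(abs(es@deltaLower - (-5.538)), 1e-3)
    expect_lt(abs(es@ciLower - (-1.751)), 1e-3)
    expect_lt(abs(es@ciUpper - (-0.214)), 1e-3)
    # abnormality: point estimate inside the percentage interval
    expect_equal(es@pctPoint, 100 * pt(-1 / sqrt(1.1), 9), tolerance = 1e-9)
    expect_equal(es@pctPoint, 18.25, tolerance = 0.01)
    expect_equal(es@pctLower, 100 * pnorm(es@ciLower))
    expect_equal(es@pctUpper, 100 * pnorm(es@ciUpper))
    expect_equal(round(c(es@pctLower, es@pctUpper), 1), c(4.0, 41.5))
    expect_true(es@pctLower < es@pctPoint && es@pctPoint < es@pctUpper)
})

test_that("the zero-effect interval has the closed normal form", {
    # at z_cc = 0 the noncentral t CDF at 0 equals pnorm(-delta)
    for (n in c(5L, 12L, 40L)) {
        es <- effectSizeInterval(0.5, controlSummary(mean = 0.5, sd = 0.1,
                                                     n = n))
        expect_equal(es@ciLower, -qnorm(0.975) / sqrt(n), tolerance = 1e-6)
        expect_equal(es@ciUpper, qnorm(0.975) / sqrt(n), tolerance = 1e-6)
    }
})

test_that("interval consistency: covers z_cc, narrows with n", {
    set.seed(11)
    for (i in 1:25) {
        es <- effectSizeInterval(rnorm(1, 0, 2),
                                 controlSummary(mean = 0, sd = 1,
                                                n = sample(3:40, 1)))
        expect_lte(es@ciLower, es@zcc)
        expect_gte(es@ciUpper, es@zcc)
    }
    widths <- vapply(c(5L, 10L, 20L, 50L, 200L), function(n) {
        es <- effectSizeInterval(0.4, controlSummary(mean = 0.5, sd = 0.1,
                                                     n = n))
        es@ciUpper - es@ciLower
    }, 0)
    expect_true(all(diff(widths) < 0))
})

test_that("95% interval coverage is nominal over normal replicates", {
    set.seed(1)
    nrep <- 2000
    covered <- logical(nrep)
    for (i in seq_len(nrep)) {
        ctl <- controlSummary(rnorm(10))       # N(0, 1) controls
        es <- effectSizeInterval(-1, ctl)      # case at population z = -1
        covered[i] <- es@ciLower <= -1 && -1 <= es@ciUpper
    }
    mcSE <- sqrt(0.95 * 0.05 / nrep)
    expect_lt(abs(mean(covered) - 0.95), 2 * mcSE)
})

test_that("batch application matches the scalar tests and flags bad rows", {
    ctl <- exactControls(10, 0.5, 0.1)
    res <- batchSingleCase(0.4, matrix(ctl, nrow = 1), method = "CH")
    expect_equal(res$statistic, -1 / sqrt(1.1), tolerance = 1e-10)
    expect_identical(res$df, 9L)
    expect_identical(res$effectiveN, 10L)

    # missing controls are dropped per row, with the effective n recorded
    m <- rbind(c(ctl, NA, NA), c(rep(0.5, 11), NA), c(0.2, 0.3, rep(NA, 10)))
    res <- batchSingleCase(c(0.4, 0.4, 0.4), m, method = "CH",
                           minControls = 3L)
    expect_identical(res$effectiveN, c(10L, 11L, 2L))
    expect_equal(res$statistic[1], -1 / sqrt(1.1), tolerance = 1e-10)
    expect_false(res$untestable[1])
    expect_true(res$untestable[3])          # < 3 usable controls
    expect_true(is.na(res$statistic[3]))    # flagged, not dropped

    # zero-variance rows: only a discrepant case is untestable
    z <- rbind(rep(0.5, 10), rep(0.5, 10))
    res <- batchSingleCase(c(0.5, 0.6), z, method = "CH")
    expect_identical(res$statistic[1], 0)
    expect_true(res$untestable[2])
})

test_that("empirical type I error: CH nominal, OS inflated, WB below CH", {
    rates <- type1ErrorExperiment(nReps = 20000, nControls = 20,
                                  method = c("CH", "OS", "WB"), seed = 2)
    binomTol <- 3 * sqrt(0.05 * 0.95 / 20000)
    expect_lt(abs(rates["CH"] - 0.05), binomTol)
    expect_gt(rates["OS"], rates["CH"])
    expect_lte(rates["WB"], rates["CH"])

    ratesSmall <- type1ErrorExperiment(nReps = 20000, nControls = 10,
                                       method = "OS", seed = 2)
    expect_gt(ratesSmall, 0.07)
})
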