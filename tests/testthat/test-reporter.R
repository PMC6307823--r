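test_that("relative abundance averages transformed Ct values, not Ct means", {
    expect_equal(relativeAbundance(c(10, 10, 10), c(10, 10, 10)), 1.0)
    expect_equal(relativeAbundance(c(11, 11, 11), c(10, 10, 10)), 0.5)
    # transform-then-average differs from the naive 2^-(mean dCt)
    expect_equal(relativeAbundance(c(10, 11, 12), c(10, 10, 10)),
                 (1 + 0.5 + 0.25) / 3)
    expect_false(isTRUE(all.equal(relativeAbundance(c(10, 11, 12), c(10, 10, 10)),
                                  2^-(mean(c(10, 11, 12)) - 10))))
    expect_error(relativeAbundance(numeric(), c(10, 10, 10)), "non-empty")
    expect_error(relativeAbundance(c(10, NA, 10), c(10, 10, 10)), "finite")
})

test_that("relative abundance is invariant to a common Ct shift", {
    set.seed(11)
    for (i in 1:20) {
        rep <- runif(3, 8, 30); ref <- runif(3, 8, 30)
        shift <- runif(1, -5, 5)
        expect_equal(relativeAbundance(rep - shift, ref - shift),
                     relativeAbundance(rep, ref))
    }
})

test_that("protein normalization is an elementwise ratio", {
    expect_equal(normalizeProtein(5, 5), 1)
    expect_equal(normalizeProtein(3, 6), 0.5)
    expect_equal(normalizeProtein(c(1, 2, 3), c(2, 2, 2)), c(0.5, 1, 1.5))
    expect_error(normalizeProtein(1, 0), "positive")
})

test_that("replicate summaries match hand arithmetic and a two-pass oracle", {
    s <- summarizeExpression(c(1, 1, 1, 1))
    expect_equal(c(s$mean, s$sd, s$sem), c(1, 0, 0))
    s <- summarizeExpression(c(2, 4))
    expect_equal(s$mean, 3)
    expect_equal(s$sd, sqrt(2))
    expect_equal(s$sem, 1)
    set.seed(21)
    for (i in 1:25) {
        x <- rnorm(sample(2:12, 1), 10, 3)
        s <- summarizeExpression(x)
        expect_equal(s$sd^2, oracleVar(x))
        expect_equal(s$sem, sqrt(oracleVar(x) / length(x)))
    }
    expect_error(summarizeExpression(5), "at least 2")
})

test_that("ratio of means propagates SEM via relative errors", {
    mk <- function(m, se, n = 3) list(mean = m, sem = se, n = n)
    r <- ratioOfMeans(mk(10, 0), mk(10, 0))
    expect_equal(ratioValue(r), 1)
    expect_equal(propagatedSem(r), 0)
    r <- ratioOfMeans(mk(2, 0.2), mk(4, 0.2))
    expect_equal(ratioValue(r), 0.5)
    expect_equal(propagatedSem(r), 0.5 * sqrt(0.01 + 0.0025))
    expect_equal(propagatedSem(r), 0.05590, tolerance = 1e-4)
    # self-ratio: exactly (1, sqrt(2) * sem/mean)
    s <- mk(7, 0.35, 4)
    rs <- ratioOfMeans(s, s)
    expect_equal(ratioValue(rs), 1)
    expect_equal(propagatedSem(rs), sqrt(2) * 0.35 / 7)
    expect_error(ratioOfMeans(mk(2, 0.1), mk(0, 0.1)), "positive")
})

test_that("propagated SEM tracks the Monte-Carlo SD of the ratio at small CV", {
    set.seed(31)
    n <- 4
    for (cv in c(0.02, 0.05, 0.1)) {
        X <- 2; Y <- 5
        ratios <- replicate(4000, {
            a <- rnorm(n, X, cv * X); b <- rnorm(n, Y, cv * Y)
            mean(a) / mean(b)
        })
        prop <- propagatedSem(ratioOfMeans(
            list(mean = X, sem = cv * X / sqrt(n), n = n),
            list(mean = Y, sem = cv * Y / sqrt(n), n = n)))
        expect_equal(sd(ratios), prop, tolerance = 0.1)
    }
})

test_that("paired delta-TE is the per-pair quotient of repression ratios", {
    d <- pairedDeltaTE(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
    expect_equal(d$perPair, c(1, 1, 1))
    expect_equal(d$mean, 1)
    # protein ratio 0.2 vs mRNA ratio 0.4 halves the TE
    d <- pairedDeltaTE(c(0.2, 0.2, 0.2), c(1, 1, 1), c(0.4, 0.4, 0.4), c(1, 1, 1))
    expect_equal(d$mean, 0.5)
    # equal repression of protein and mRNA leaves TE unchanged
    d <- pairedDeltaTE(c(0.4, 0.4, 0.4), c(1, 1, 1), c(0.4, 0.4, 0.4), c(1, 1, 1))
    expect_equal(d$mean, 1)
    expect_error(pairedDeltaTE(1:2, 1:2, 1:2, 1:2), "3 replicate pairs")
    expect_error(pairedDeltaTE(1:3, c(0, 1, 1), 1:3, 1:3), "positive")
})

test_that("unpaired t-test equals the textbook pooled formula", {
    r <- unpairedTTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$t, 0)
    expect_equal(r$p, 1)
    o <- oracleStudentT(c(1, 2, 3), c(2, 3, 4))
    r <- unpairedTTest(c(1, 2, 3), c(2, 3, 4))
    expect_equal(r$t, o$t, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
    set.seed(41)
    for (i in 1:1000) {
        a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), sample(0:2, 1))
        r <- unpairedTTest(a, b)
        o <- oracleStudentT(a, b)
        expect_equal(r$t, o$t, tolerance = 1e-10)
        expect_equal(r$p, o$p, tolerance = 1e-10)
        expect_equal(r$df, o$df)
    }
})

test_that("p decreases monotonically as the mean separation grows", {
    set.seed(51)
    base <- rnorm(5)
    ps <- vapply(c(0.5, 1, 2, 4), function(d)
        unpairedTTest(base, base + d)$p, numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("degenerate zero-variance groups follow the stated convention", {
    expect_equal(unpairedTTest(c(2, 2), c(2, 2))$p, 1)
    expect_equal(unpairedTTest(c(2, 2), c(3, 3))$p, 0)
})

test_that("significance labels use the study's strict cutoffs", {
    expect_equal(significanceLabel(0.005), "**")
    expect_equal(significanceLabel(0.03), "*")
    expect_equal(significanceLabel(0.05), "n.s.")
    expect_equal(significanceLabel(0.01), "*")
    expect_equal(significanceLabel(c(0.2, 0.001)), c("n.s.", "**"))
    expect_error(significanceLabel(1.2), "\\[0, 1\\]")
})

test_that("zero-noise simulated reporter experiments recover construct effects exactly", {
    cfg <- zeroNoiseConfig()
    samples <- simulateReporterExperiment(
        cfg, list("MS2-F" = c(1, 1), "Scd6-MS2-F" = c(0.4, 0.4)),
        nBioreps = 3)
    res <- analyzeReporter(samples, "Scd6-MS2-F", "MS2-F")
    expect_equal(res$protein_ratio, 0.4)
    expect_equal(res$mrna_ratio, 0.4)
    expect_equal(res$protein_sem, 0)
    expect_equal(res$dte_mean, 1)
})

test_that("noisy reporter recovery lands within three propagated SEMs", {
    hits <- 0
    nSeeds <- 60
    for (s in seq_len(nSeeds)) {
        cfg <- simConfig(seed = 2000 + s, measurementCv = 0.1, ctSd = 0.15)
        samples <- simulateReporterExperiment(
            cfg, list("MS2-F" = c(1, 1), "Scd6-MS2-F" = c(0.4, 0.4)),
            nBioreps = 6)
        res <- analyzeReporter(samples, "Scd6-MS2-F", "MS2-F")
        if (abs(res$mrna_ratio - 0.4) <= 3 * res$mrna_sem) hits <- hits + 1
    }
    expect_gte(hits / nSeeds, 0.9)
})
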