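test_that("config validation rejects malformed parameters", {
    expect_error(simConfig(fracMrnaUp = 1.2), "\\[0, 1\\]")
    expect_error(simConfig(mrnaEffectFold = -1), "positive")
    expect_error(simConfig(timepointsMin = c(2, 4)), "first element 0")
    expect_error(simConfig(timepointsMin = c(0, 4, 4)), "strictly increasing")
    expect_error(simConfig(ripCorrelation = 1), "\\|r\\| < 1")
    expect_error(simulateCounts(simConfig(nGenes = 50)), ">= 100")
    expect_error(simulateDecaySeries(-0.1, simConfig()), "positive")
    expect_error(simulateGradient(1, nFractions = 1), ">= 2")
    expect_error(simulateReporterExperiment(
        simConfig(), list(A = c(0.5, 0.5))), "reference construct")
    expect_error(simulateReporterExperiment(
        simConfig(), list(A = c(1, 1), B = c(-2, 1))), "positive folds")
})

test_that("identical configs reproduce byte-identical outputs", {
    cfg <- simConfig(seed = 99, nGenes = 150)
    eff <- list("MS2-F" = c(1, 1), "X" = c(0.5, 0.6))
    expect_identical(simulateReporterExperiment(cfg, eff),
                     simulateReporterExperiment(cfg, eff))
    expect_identical(simulateDecaySeries(0.3, cfg), simulateDecaySeries(0.3, cfg))
    expect_identical(simulateGradient(7, seed = 5, cv = 0.2, nBioreps = 2),
                     simulateGradient(7, seed = 5, cv = 0.2, nBioreps = 2))
    a <- simulateCounts(cfg); b <- simulateCounts(cfg)
    expect_identical(rnaCounts(a$experiment), rnaCounts(b$experiment))
    expect_identical(rpfCounts(a$experiment), rpfCounts(b$experiment))
    expect_identical(simulateCovariates(a$truth, cfg),
                     simulateCovariates(b$truth, cfg))
})

test_that("simulated counts satisfy the NB mean-variance relationship", {
    cfg <- simConfig(seed = 5, nGenes = 1200, genotypes = "WT", nBioreps = 40,
                     fracMrnaUp = 0, fracTeDown = 0, dispersion = 5,
                     libSizeSd = 0)
    sim <- simulateCounts(cfg)
    m <- rnaCounts(sim$experiment)
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    expected <- mu + mu^2 / 5
    expect_equal(median(v / expected), 1, tolerance = 0.1)
})

test_that("the Poisson limit gives variance equal to the mean", {
    cfg <- simConfig(seed = 6, nGenes = 1000, genotypes = "WT", nBioreps = 40,
                     fracMrnaUp = 0, fracTeDown = 0, dispersion = Inf,
                     libSizeSd = 0)
    m <- rnaCounts(simulateCounts(cfg)$experiment)
    ratio <- apply(m, 1, var) / rowMeans(m)
    expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("truth table carries unit WT folds and one row per emitted gene", {
    sim <- simulateCounts(simConfig(seed = 2, nGenes = 300))
    expect_true(all(sim$truth$mrna_fold_WT == 1))
    expect_true(all(sim$truth$te_fold_WT == 1))
    expect_identical(sim$truth$gene_id, rownames(sim$experiment))
    expect_false(anyDuplicated(sim$truth$gene_id) > 0)
})

test_that("epistasis nulls single-mutant effects on the dcp2d background", {
    sim <- simulateCounts(simConfig(seed = 3, nGenes = 300))
    tr <- sim$truth
    expect_true(any(tr$mrna_fold_scd6d > 1))
    expect_true(all(tr$mrna_fold_dcp2d_scd6d == 1))
    expect_true(all(tr$te_fold_dcp2d_dhh1d == 1))
    # switched off, the double mutant inherits the single-mutant effect
    sim2 <- simulateCounts(simConfig(seed = 3, nGenes = 300, epistasis = FALSE))
    expect_identical(sim2$truth$mrna_fold_dcp2d_scd6d, sim2$truth$mrna_fold_scd6d)
})

test_that("decay series follow first-order kinetics and normalize to 100", {
    cfg <- simConfig(seed = 4, timepointsMin = c(0, 1, 2), decayNoiseCv = 0)
    d <- simulateDecaySeries(0.693, cfg, nBioreps = 1)
    expect_equal(d$relative_abundance[d$time_min == 0], 100)
    expect_equal(d$relative_abundance[d$time_min == 1], 100 * exp(-0.693))
    expect_equal(round(d$relative_abundance[d$time_min == 1], 1), 50.0)
    dn <- simulateDecaySeries(0.3, simConfig(seed = 4), nBioreps = 3)
    expect_equal(as.numeric(tapply(dn$relative_abundance, dn$bioreplicate,
                                   function(v) v[1])), rep(100, 3))
})

test_that("gradient profiles are unimodal and collapse to the peak at zero spread", {
    g <- simulateGradient(7, 15, spread = 0)
    expect_equal(fractionDistribution(g$signal)[7], 100)
    g <- simulateGradient(4, 15, spread = 1.2, seed = 8)
    expect_equal(which.max(g$signal), 4)
    expect_equal(sum(g$signal), 1)
    expect_error(simulateGradient(20, 15), "peakFraction")
})

test_that("simulated covariates hit their target correlation and sTAI mean", {
    cfg0 <- simConfig(seed = 9, nGenes = 5000, ripCorrelation = 0)
    sim <- simulateCounts(cfg0)
    tr <- simulateCovariates(sim$truth, cfg0)
    x <- log2(tr$te_fold_dhh1d)
    expect_lt(abs(cor(tr$rip_enrichment, x)), 0.05)

    cfg3 <- simConfig(seed = 10, nGenes = 3695, ripCorrelation = 0.3)
    tr3 <- simulateCovariates(simulateCounts(cfg3)$truth, cfg3)
    r <- cor(tr3$rip_enrichment, log2(tr3$te_fold_dhh1d))
    expect_gte(r, 0.25); expect_lte(r, 0.35)

    cfg6 <- simConfig(seed = 11, nGenes = 6000)
    tr6 <- simulateCovariates(simulateCounts(cfg6)$truth, cfg6)
    expect_equal(mean(tr6$stai), 0.35, tolerance = 0.01 / 0.35)
    expect_true(all(tr6$stai > 0 & tr6$stai < 1))
})

test_that("reporter simulation responds to strain modifiers", {
    cfg <- zeroNoiseConfig()
    samples <- simulateReporterExperiment(
        cfg, list("MS2-F" = c(1, 1), "Scd6-MS2-F" = c(0.4, 0.4)),
        strains = c("WT", "dcp2d_dhh1d"), nBioreps = 3,
        strainModifiers = list("dcp2d_dhh1d" = c(2.5, 2.5)))
    res <- analyzeReporter(samples, "Scd6-MS2-F", "MS2-F")
    expect_equal(res$mrna_ratio[res$strain == "WT"], 0.4)
    expect_equal(res$mrna_ratio[res$strain == "dcp2d_dhh1d"], 1.0)
})
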