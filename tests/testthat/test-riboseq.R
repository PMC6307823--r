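# Small hand-checkable experiment: 5 genes, 2 genotypes x 2 replicates.
fiveGeneFixture <- function() {
    rna <- matrix(c(3, 3, 2, 2,      # total 10: kept at the boundary
                    2, 3, 2, 2,      # total 9: removed
                    100, 110, 95, 105,
                    50, 55, 45, 50,
                    0, 0, 0, 0),
                  nrow = 5, byrow = TRUE,
                  dimnames = list(paste0("g", 1:5),
                                  c("WT_r1", "WT_r2", "mut_r1", "mut_r2")))
    rpf <- matrix(c(6, 6, 4, 4,
                    4, 6, 4, 4,
                    200, 220, 190, 210,
                    25, 28, 22, 25,
                    0, 0, 0, 0),
                  nrow = 5, byrow = TRUE, dimnames = dimnames(rna))
    TranslatomeExperiment(rna, rpf,
                          genotype = c("WT", "WT", "mut", "mut"),
                          bioreplicate = c(1, 2, 1, 2))
}

test_that("the minimum-total read filter is inclusive at the boundary", {
    x <- fiveGeneFixture()
    spec <- contrastSpec("mut", "WT", "mRNA")
    kept <- filterGenes(x, spec, minTotal = 10)
    expect_true("g1" %in% kept)    # 3+3+2+2 = 10 kept
    expect_false("g2" %in% kept)   # 2+3+2+2 = 9 removed
    expect_identical(filterGenes(x, spec, minTotal = 0), rownames(x))
})

test_that("library normalization equalizes totals with hand-computed factors", {
    m <- matrix(c(4e5, 6e5, 8e5, 1.2e6), 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    # totals 1e6 and 2e6 -> factors 1.5 and 0.75, both scaled to 1.5e6
    r <- libraryNormalize(m)
    expect_equal(unname(r$factors), c(1.5, 0.75))
    expect_equal(unname(colSums(r$counts)), c(1.5e6, 1.5e6))
    same <- matrix(c(10, 20, 15, 15), 2)
    expect_equal(unname(libraryNormalize(same)$factors), c(1, 1))
    set.seed(101)
    rnd <- matrix(rpois(60, 50) + 1, 6)
    tot <- colSums(libraryNormalize(rnd)$counts)
    expect_lt(diff(range(tot)) / mean(tot), 1e-6)
    expect_error(libraryNormalize(cbind(same, 0)), "positive total")
})

test_that("the wiggle factor scales reads to per-1000-million units", {
    expect_equal(wiggleFactor(1e9), 1)
    expect_equal(wiggleFactor(5e8), 2)
    expect_equal(wiggleFactor(2.5e8), 4)
    expect_error(wiggleFactor(0), "positive")
    f <- tempfile(fileext = ".wig")
    writeWiggle(c(2, 4, 6), "chrI", f, factor = wiggleFactor(5e8))
    lines <- readLines(f)
    expect_match(lines[2], "fixedStep chrom=chrI start=1 step=1")
    expect_equal(as.numeric(lines[3:5]), c(4, 8, 12))
})

test_that("TE pools replicates by summation and flags zero-RNA genes", {
    rna <- matrix(c(150, 0, 10, 100, 0, 60), 3,
                  dimnames = list(c("g1", "g2", "g3"), c("a_r1", "a_r2")))
    rpf <- matrix(c(300, 5, 10, 300, 5, 10), 3, dimnames = dimnames(rna))
    x <- TranslatomeExperiment(rna, rpf, genotype = c("a", "a"),
                               bioreplicate = 1:2)
    # equal library totals (160/160 and 315/315): normalization is identity
    te <- computeTE(x, "a")
    expect_equal(unname(te["g1"]), (300 + 300) / (150 + 100))
    expect_true(is.na(te["g2"]))
    expect_equal(unname(te["g3"]), (10 + 10) / (10 + 60))
    x2 <- TranslatomeExperiment(rna, rpf * 2, genotype = c("a", "a"),
                                bioreplicate = 1:2)
    expect_equal(computeTE(x2, "a")[c(1, 3)], te[c(1, 3)] * 2)
    expect_error(computeTE(x, "zzz"), "no samples")
})

test_that("self-contrast gives zero log-changes and the dTE identity holds", {
    x <- fiveGeneFixture()
    rna <- rnaCounts(x); rpf <- rpfCounts(x)
    rnaDup <- cbind(rna[, 1:2], rna[, 1:2])
    rpfDup <- cbind(rpf[, 1:2], rpf[, 1:2])
    colnames(rnaDup) <- colnames(rpfDup) <- paste0("s", 1:4)
    dup <- TranslatomeExperiment(rnaDup, rpfDup,
                                 genotype = c("WT", "WT", "mut", "mut"),
                                 bioreplicate = c(1, 2, 1, 2))
    st <- contrastStats(dup, contrastSpec("mut", "WT", "mRNA"), minTotal = 10)
    expect_true(all(abs(st$log2_dmrna) < 1e-12))
    expect_true(all(abs(st$log2_dte) < 1e-12, na.rm = TRUE))

    st2 <- contrastStats(x, contrastSpec("mut", "WT", "TE"), minTotal = 1)
    ok <- !is.na(st2$log2_dte)
    expect_equal(st2$log2_dte[ok], (st2$log2_drpf - st2$log2_dmrna)[ok],
                 tolerance = 1e-9)
})

test_that("simulated TE effects are recovered at the right magnitude", {
    cfg <- simConfig(seed = 111, nGenes = 1500)
    sim <- simulateCounts(cfg)
    st <- contrastStats(sim$experiment, contrastSpec("dhh1d", "WT", "TE"))
    down <- sim$truth$gene_id[sim$truth$te_fold_dhh1d < 1]
    med <- 2^median(st$log2_dte[st$gene_id %in% down], na.rm = TRUE)
    expect_equal(med, 0.5, tolerance = 0.12)
    # unaffected genes center near zero change
    null <- setdiff(st$gene_id, down)
    expect_lt(abs(median(st$log2_dte[st$gene_id %in% null], na.rm = TRUE)), 0.1)
})

test_that("stand-in test is calibrated on effect-free contrasts", {
    cfg <- simConfig(seed = 112, nGenes = 3000)
    sim <- simulateCounts(cfg)
    # WT and dcp2d both carry no simulated effects: a true null contrast
    td <- testDifferential(sim$experiment, contrastSpec("dcp2d", "WT", "mRNA"))
    expect_gt(mean(td$p < 0.05), 0.02)
    expect_lt(mean(td$p < 0.05), 0.08)
    expect_equal(td$fdr, oracleBH(td$p))
})

test_that("stand-in test has power on strong effects, matching the normal approximation", {
    cfg <- simConfig(seed = 113, nGenes = 3000, baseMeanRange = c(500, 500),
                     fracMrnaUp = 0.02, mrnaEffectFold = 4, fracTeDown = 0,
                     genotypes = c("WT", "scd6d"), libSizeSd = 0)
    sim <- simulateCounts(cfg)
    td <- testDifferential(sim$experiment, contrastSpec("scd6d", "WT", "mRNA"))
    up <- sim$truth$gene_id[sim$truth$mrna_fold_scd6d > 1]
    power <- mean(td$p[td$gene_id %in% up] < 0.01)
    # analytic oracle: Z ~ N(lnFC/SE, 1); SE^2 = 2 * (1/mu + alpha)/n, and the
    # equal-total normalization shifts the observed fold by ~2% truth fraction
    se <- sqrt(2 * (1 / 500 + 1 / cfg$dispersion) / 2)
    shift <- 1 + cfg$fracMrnaUp * (cfg$mrnaEffectFold - 1)
    predicted <- pnorm(log(4 / shift) / se - qnorm(0.995))
    expect_equal(power, predicted, tolerance = 0.08)
    expect_gt(power, 0.8)
})

test_that("all-zero genes get p = 1 and never enter gene sets", {
    x <- fiveGeneFixture()
    td <- testDifferential(x, contrastSpec("mut", "WT", "mRNA"), minTotal = 0)
    expect_equal(td$p[td$gene_id == "g5"], 1)
})

test_that("gene-set selection respects inclusive fold and alpha conventions", {
    st <- data.frame(gene_id = paste0("g", 1:4),
                     log2_dmrna = log2(c(1.39, 1.4, 2.0, 0.5)),
                     log2_drpf = 0, log2_dte = 0,
                     p = c(0.001, 0.001, 0.5, 0.001),
                     fdr = c(0.005, 0.005, 0.5, 0.005))
    gs <- selectSet(st, "mRNA", minFold = 1.4, alpha = 0.01, alphaType = "FDR",
                    direction = "up")
    expect_identical(geneIds(gs), "g2")   # 1.39 excluded, 1.4 kept, g3 not sig.
    all <- selectSet(st, "mRNA", minFold = 1, alpha = 1, alphaType = "p")
    expect_identical(geneIds(all), st$gene_id)
    down <- selectSet(st, "mRNA", minFold = 1.4, alpha = 0.01,
                      alphaType = "FDR", direction = "down")
    expect_identical(geneIds(down), "g4")
    expect_error(selectSet(st, "mRNA", minFold = 0.5, alpha = 0.01), ">= 1")
    expect_identical(selectionRule(gs)$minFold, 1.4)
})

test_that("set response shows the epistasis signature across the panel", {
    cfg <- simConfig(seed = 114, nGenes = 2000)
    sim <- simulateCounts(cfg)
    x <- sim$experiment
    up <- sim$truth$gene_id[sim$truth$mrna_fold_scd6d > 1]
    set <- new("GeneSet", name = "truth_up", geneIds = up, selection = list())
    tables <- list(
        scd6d_vs_WT = contrastStats(x, contrastSpec("scd6d", "WT", "mRNA")),
        dcp2d_scd6d_vs_dcp2d = contrastStats(
            x, contrastSpec("dcp2d_scd6d", "dcp2d", "mRNA")))
    resp <- setResponse(set, tables, "mRNA")
    expect_gt(resp$scd6d_vs_WT$stats$median, 0.7)
    expect_lt(abs(resp$dcp2d_scd6d_vs_dcp2d$stats$median), 0.15)
    # unaffected genes stay centered in every contrast
    nullSet <- new("GeneSet", name = "null",
                   geneIds = sample(setdiff(sim$truth$gene_id, up), 300),
                   selection = list())
    respNull <- setResponse(nullSet, tables, "mRNA")
    expect_lt(abs(respNull$scd6d_vs_WT$stats$median), 0.15)
    expect_lte(length(resp$scd6d_vs_WT$values) + resp$scd6d_vs_WT$nDropped,
               length(up))
})

test_that("clustering pre-filter drops extremes and partitions at +/- 2", {
    tab <- data.frame(gene_id = paste0("g", 1:5),
                      scd6d = c(4.5, 1.9, 2.5, 0.0, NA),
                      dhh1d = c(0.1, -1.9, 0.1, 0.3, 0.2))
    r <- clusteringPrefilter(tab)
    expect_identical(r$dropped, c("g1", "g5"))
    expect_identical(r$inner, c("g2", "g4"))
    expect_identical(r$outer, "g3")
})

test_that("external significance columns can replace the stand-in's", {
    x <- fiveGeneFixture()
    st <- contrastStats(x, contrastSpec("mut", "WT", "mRNA"), minTotal = 0)
    ext <- data.frame(gene_id = st$gene_id, p = rep(0.2, nrow(st)))
    st2 <- importExternalStats(st, ext)
    expect_true(all(st2$p == 0.2))
    expect_true(all(st2$fdr == 0.2))
})
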