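# Genome-wide Ribo-seq/RNA-Seq stage: gene filtering, equal-total library
# normalization, translational efficiency (TE) per genotype, per-gene
# contrast statistics, a negative-binomial Wald stand-in significance test,
# threshold-based gene-set selection, epistasis contrasts, and the
# clustering pre-filter/partition.

#' Specify a two-genotype contrast
#'
#' @param mutant,baseline genotype labels; baseline is WT for single mutants
#'   and the dcp2d single mutant for dcp2d-containing double mutants
#'   (epistasis contrasts).
#' @param metric which quantity the contrast's significance test addresses:
#'   "mRNA", "RPF" or "TE".
#' @return list of class "ContrastSpec".
#' @export
contrastSpec <- function(mutant, baseline = "WT",
                         metric = c("mRNA", "RPF", "TE")) {
    metric <- match.arg(metric)
    if (identical(mutant, baseline))
        stop("mutant and baseline genotypes must differ")
    structure(list(mutant = mutant, baseline = baseline, metric = metric),
              class = "ContrastSpec")
}

contrastSamples <- function(x, spec) {
    g <- genotypes(x)
    if (!all(c(spec$mutant, spec$baseline) %in% g))
        stop(sprintf("genotype(s) not in experiment: %s (available: %s)",
                     paste(setdiff(c(spec$mutant, spec$baseline), g), collapse = ", "),
                     paste(unique(g), collapse = ", ")))
    list(mutant = which(g == spec$mutant), baseline = which(g == spec$baseline))
}

#' Filter genes by total mRNA reads in a contrast
#'
#' Keeps genes whose raw RNA counts summed over the contrast's samples reach
#' \code{minTotal} (default 10, applied to the 4 samples of a standard
#' two-replicate contrast; the rule scales to however many samples the
#' contrast has).
#'
#' @param x a \linkS4class{TranslatomeExperiment}.
#' @param spec a \code{\link{contrastSpec}}.
#' @param minTotal minimum summed RNA count (inclusive).
#' @return character vector of retained gene ids.
#' @export
filterGenes <- function(x, spec, minTotal = 10) {
    if (nrow(x) == 0) stop("empty count matrix")
    idx <- contrastSamples(x, spec)
    tot <- rowSums(rnaCounts(x)[, c(idx$mutant, idx$baseline), drop = FALSE])
    rownames(x)[tot >= minTotal]
}

#' Equal-total library normalization
#'
#' Scales each sample's counts so that all samples have the same total (the
#' mean library size); returns the scaled matrix and the per-sample factors.
#' This is the normalization that makes the median log2 change across genes
#' approximately zero in a contrast.
#'
#' @param m gene-by-sample count matrix (every sample total > 0).
#' @return list(counts = scaled matrix, factors = named per-sample factors).
#' @export
libraryNormalize <- function(m) {
    m <- as.matrix(m)
    totals <- colSums(m)
    if (any(totals <= 0)) stop("every sample must have a positive total")
    f <- mean(totals) / totals
    list(counts = sweep(m, 2, f, `*`), factors = f)
}

#' Wiggle-track normalization factor
#'
#' q = 1,000,000,000 / total mapped reads — scales per-position read counts
#' to reads per 1,000 million total reads for browser display.
#'
#' @param totalReads total reads on both strands (> 0).
#' @return the scalar factor q.
#' @export
wiggleFactor <- function(totalReads) {
    if (any(totalReads <= 0)) stop("total reads must be positive")
    1e9 / totalReads
}

#' Write a fixed-step wiggle track
#'
#' @param values per-position values (already counted).
#' @param chrom chromosome name.
#' @param file output path.
#' @param start 1-based start position.
#' @param step step size in bp.
#' @param factor scaling factor, e.g. from \code{\link{wiggleFactor}}.
#' @param name track name.
#' @return the file path, invisibly.
#' @export
writeWiggle <- function(values, chrom, file, start = 1L, step = 1L,
                        factor = 1, name = "track") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(sprintf("track type=wiggle_0 name=\"%s\"", name),
                 sprintf("fixedStep chrom=%s start=%d step=%d",
                         chrom, as.integer(start), as.integer(step)),
                 format(values * factor, trim = TRUE, scientific = FALSE)),
               con)
    invisible(file)
}

#' Translational efficiency per genotype
#'
#' TE_g = (sum of normalized RPF counts over the genotype's samples) /
#' (sum of normalized RNA counts over the same genes and the genotype's RNA
#' samples). Replicates are pooled by summation; genes with zero RNA sum get
#' an undefined (NA) TE unless a pseudocount is supplied.
#'
#' @param x a \linkS4class{TranslatomeExperiment}; counts are equal-total
#'   normalized per assay before summing.
#' @param genotype genotype label (>= 1 sample required).
#' @param genes optional gene subset.
#' @param pseudocount added to both sums (default 0: zeros stay undefined).
#' @return named numeric vector of TE values.
#' @export
computeTE <- function(x, genotype, genes = rownames(x), pseudocount = 0) {
    g <- genotypes(x)
    if (!genotype %in% g) stop("no samples for genotype: ", genotype)
    sel <- which(g == genotype)
    rna <- libraryNormalize(rnaCounts(x))$counts[genes, sel, drop = FALSE]
    rpf <- libraryNormalize(rpfCounts(x))$counts[genes, sel, drop = FALSE]
    num <- rowSums(rpf) + pseudocount
    den <- rowSums(rna) + pseudocount
    te <- num / den
    te[den == 0] <- NA_real_
    te
}

#' Per-gene contrast statistics
#'
#' For a mutant-vs-baseline contrast: equal-total normalizes each assay
#' across the contrast's samples, pools replicates by summation, and returns
#' per gene the log2 changes in mRNA, RPF and TE (log2 dTE = log2 dRPF -
#' log2 dmRNA by construction), the genotype TE values, and p/FDR from the
#' negative-binomial stand-in test for the contrast's metric
#' (Benjamini-Hochberg across retained genes). Genes with an undefined TE
#' carry NA log2 dTE and are excluded from downstream medians.
#'
#' @param x a \linkS4class{TranslatomeExperiment}.
#' @param spec a \code{\link{contrastSpec}}.
#' @param minTotal gene filter threshold (see \code{\link{filterGenes}}).
#' @param pseudocount optional pseudocount for TE sums (default 0).
#' @param priorDf shrinkage prior degrees of freedom for the dispersion
#'   trend (see \code{\link{testDifferential}}).
#' @return data.frame(gene_id, te_mutant, te_baseline, log2_dmrna,
#'   log2_drpf, log2_dte, p, fdr).
#' @export
contrastStats <- function(x, spec, minTotal = 10, pseudocount = 0,
                          priorDf = 10) {
    genes <- filterGenes(x, spec, minTotal)
    idx <- contrastSamples(x, spec)
    sub <- x[, c(idx$mutant, idx$baseline)]
    gsub <- genotypes(sub)
    rna <- libraryNormalize(rnaCounts(sub))$counts[genes, , drop = FALSE]
    rpf <- libraryNormalize(rpfCounts(sub))$counts[genes, , drop = FALSE]
    mu <- gsub == spec$mutant
    sumM <- function(m, w) rowSums(m[, w, drop = FALSE])
    rnaM <- sumM(rna, mu); rnaB <- sumM(rna, !mu)
    rpfM <- sumM(rpf, mu); rpfB <- sumM(rpf, !mu)
    teM <- (rpfM + pseudocount) / (rnaM + pseudocount)
    teB <- (rpfB + pseudocount) / (rnaB + pseudocount)
    teM[rnaM + pseudocount == 0] <- NA_real_
    teB[rnaB + pseudocount == 0] <- NA_real_
    log2Ratio <- function(a, b) ifelse(a > 0 & b > 0, log2(a / b), NA_real_)
    dmrna <- log2Ratio(rnaM, rnaB)
    drpf <- log2Ratio(rpfM, rpfB)
    dte <- drpf - dmrna
    tst <- testDifferential(x, spec, metric = spec$metric,
                            minTotal = minTotal, priorDf = priorDf)
    stopifnot(identical(tst$gene_id, genes))
    data.frame(gene_id = genes, te_mutant = teM, te_baseline = teB,
               log2_dmrna = dmrna, log2_drpf = drpf, log2_dte = dte,
               p = tst$p, fdr = tst$fdr, stringsAsFactors = FALSE,
               row.names = NULL)
}

# Moment-based NB dispersion for one normalized assay over a two-group
# design, shrunk toward a a0 + a1/mu trend (limma-style weighting by
# residual vs prior degrees of freedom), floored at 1e-8.
momentDispersion <- function(m, groups, priorDf = 10) {
    lev <- unique(groups)
    rss <- 0; meanTerm <- 0; sqTerm <- 0; df <- 0
    means <- list()
    for (g in lev) {
        sel <- groups == g
        n <- sum(sel)
        mg <- rowMeans(m[, sel, drop = FALSE])
        means[[g]] <- mg
        if (n > 1) {
            rss <- rss + rowSums((m[, sel, drop = FALSE] - mg)^2)
            meanTerm <- meanTerm + (n - 1) * mg
            sqTerm <- sqTerm + (n - 1) * mg^2
            df <- df + (n - 1)
        }
    }
    alphaHat <- ifelse(sqTerm > 0, (rss - meanTerm) / sqTerm, 0)
    muAll <- rowMeans(m)
    # trend alpha(mu) = a0 + a1/mu, fitted on moment estimates (clipped at 0)
    ok <- is.finite(alphaHat) & muAll > 0
    a0 <- 0; a1 <- 0
    if (sum(ok) >= 10) {
        cap <- quantile(alphaHat[ok], 0.98)
        y <- pmin(pmax(alphaHat[ok], 0), cap)
        fit <- tryCatch(lm(y ~ I(1 / muAll[ok])), error = function(e) NULL)
        if (!is.null(fit)) {
            a0 <- max(coef(fit)[1], 0)
            a1 <- max(coef(fit)[2], 0)
        }
    }
    trend <- a0 + a1 / pmax(muAll, 1e-8)
    shrunk <- (df * pmax(alphaHat, 0) + priorDf * trend) / (df + priorDf)
    list(alpha = pmax(shrunk, 1e-8), means = means, residDf = df)
}

# Wald statistic pieces for one assay: natural-log fold change and its
# squared standard error, from group means and shrunk dispersion.
waldPieces <- function(m, groups, mutant, priorDf) {
    disp <- momentDispersion(m, groups, priorDf)
    lev <- unique(groups)
    base <- setdiff(lev, mutant)
    m1 <- disp$means[[mutant]]; m0 <- disp$means[[base]]
    n1 <- sum(groups == mutant); n0 <- sum(groups == base)
    f1 <- pmax(m1, 0.5); f0 <- pmax(m0, 0.5)
    lfc <- log(f1 / f0)
    se2 <- (1 / f1 + disp$alpha) / n1 + (1 / f0 + disp$alpha) / n0
    list(lfc = lfc, se2 = se2, allZero = m1 == 0 & m0 == 0)
}

#' Negative-binomial Wald stand-in significance test
#'
#' A self-contained per-gene test for count differences between two
#' genotypes, standing in for an external differential-expression engine:
#' per-gene dispersions are estimated by the method of moments on
#' equal-total normalized counts, shrunk toward an a0 + a1/mu trend
#' (weighting residual against prior degrees of freedom, floored at 1e-8),
#' and a Wald statistic compares the natural-log ratio of genotype means to
#' its delta-method standard error. For metric "TE" the interaction is
#' tested: the difference between the RPF and RNA log fold changes, with
#' standard errors added. Genes with all-zero counts in both genotypes get
#' p = 1. Externally computed p/FDR columns (e.g. from a dedicated
#' differential-expression package) can be substituted downstream via
#' \code{\link{importExternalStats}}.
#'
#' @param x a \linkS4class{TranslatomeExperiment}.
#' @param spec a \code{\link{contrastSpec}} (>= 2 replicates per genotype).
#' @param metric "mRNA", "RPF" or "TE" (defaults to the contrast's metric).
#' @param minTotal gene filter threshold.
#' @param priorDf prior degrees of freedom pulling per-gene dispersions
#'   toward the trend; the default 10 dominates the 2 residual df of a
#'   two-replicate design, trading per-gene adaptivity for calibration.
#' @return data.frame(gene_id, stat, p, fdr) over retained genes
#'   (Benjamini-Hochberg FDR).
#' @export
testDifferential <- function(x, spec, metric = spec$metric, minTotal = 10,
                             priorDf = 10) {
    idx <- contrastSamples(x, spec)
    if (length(idx$mutant) < 2 || length(idx$baseline) < 2)
        stop("need >= 2 replicates per genotype")
    genes <- filterGenes(x, spec, minTotal)
    sub <- x[, c(idx$mutant, idx$baseline)]
    groups <- genotypes(sub)
    rna <- libraryNormalize(rnaCounts(sub))$counts[genes, , drop = FALSE]
    rpf <- libraryNormalize(rpfCounts(sub))$counts[genes, , drop = FALSE]
    if (metric == "mRNA") {
        w <- waldPieces(rna, groups, spec$mutant, priorDf)
        z <- w$lfc / sqrt(w$se2); allZero <- w$allZero
    } else if (metric == "RPF") {
        w <- waldPieces(rpf, groups, spec$mutant, priorDf)
        z <- w$lfc / sqrt(w$se2); allZero <- w$allZero
    } else {
        wr <- waldPieces(rpf, groups, spec$mutant, priorDf)
        wn <- waldPieces(rna, groups, spec$mutant, priorDf)
        z <- (wr$lfc - wn$lfc) / sqrt(wr$se2 + wn$se2)
        allZero <- wr$allZero & wn$allZero
    }
    p <- 2 * pnorm(-abs(z))
    p[allZero] <- 1
    data.frame(gene_id = genes, stat = z, p = p, fdr = p.adjust(p, "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Substitute externally computed significance columns
#'
#' Replaces the stand-in test's p/FDR columns in a \code{\link{contrastStats}}
#' table with values computed by an external engine (matched by gene id).
#'
#' @param stats a \code{\link{contrastStats}} data.frame.
#' @param external data.frame(gene_id, p, fdr) (fdr recomputed by
#'   Benjamini-Hochberg when absent).
#' @return the stats table with p and fdr replaced.
#' @export
importExternalStats <- function(stats, external) {
    if (!all(c("gene_id", "p") %in% names(external)))
        stop("external table needs gene_id and p columns")
    i <- match(stats$gene_id, external$gene_id)
    stats$p <- external$p[i]
    stats$fdr <- if ("fdr" %in% names(external)) external$fdr[i]
                 else p.adjust(stats$p, "BH")
    stats
}

#' Select a gene set by fold-change and significance thresholds
#'
#' Genes passing |fold| >= minFold in the stated direction (inclusive) AND
#' the significance criterion: FDR < alpha for alphaType "FDR" (strict, the
#' study's convention) or p <= alpha for alphaType "p".
#'
#' @param stats a \code{\link{contrastStats}} data.frame.
#' @param metric "mRNA", "RPF" or "TE" — which log2 change column to
#'   threshold.
#' @param minFold minimum fold change (>= 1).
#' @param alpha significance cutoff.
#' @param alphaType "FDR" or "p".
#' @param direction "up" (fold >= minFold) or "down" (fold <= 1/minFold).
#' @param name set label.
#' @return a \linkS4class{GeneSet} with the selection rule recorded.
#' @export
selectSet <- function(stats, metric = c("mRNA", "RPF", "TE"), minFold,
                      alpha, alphaType = c("FDR", "p"),
                      direction = c("up", "down"), name = NULL) {
    metric <- match.arg(metric); alphaType <- match.arg(alphaType)
    direction <- match.arg(direction)
    if (minFold < 1) stop("minFold must be >= 1")
    col <- switch(metric, mRNA = "log2_dmrna", RPF = "log2_drpf",
                  TE = "log2_dte")
    lf <- stats[[col]]
    # minFold = 1 is the identity fold filter (any defined change passes)
    foldOk <- if (minFold == 1) rep(TRUE, length(lf))
              else if (direction == "up") lf >= log2(minFold)
              else lf <= -log2(minFold)
    sigOk <- if (alphaType == "FDR") stats$fdr < alpha else stats$p <= alpha
    keep <- !is.na(lf) & foldOk & !is.na(sigOk) & sigOk
    if (is.null(name))
        name <- sprintf("%s_%s%.3g_%s%.3g", metric, direction, minFold,
                        tolower(alphaType), alpha)
    new("GeneSet", name = name, geneIds = stats$gene_id[keep],
        selection = list(metric = metric, minFold = minFold, alpha = alpha,
                         alphaType = alphaType, direction = direction))
}

#' Gene-set response across a panel of contrasts
#'
#' For a selected gene set, extracts the set's log2 change vector in each
#' contrast's stats table (genes missing or undefined in a contrast are
#' dropped, with the count reported) and summarizes it with notched box-plot
#' statistics. Epistasis contrasts (double mutant vs dcp2d) enter simply as
#' members of the panel.
#'
#' @param set a \linkS4class{GeneSet}.
#' @param statsTables named list of \code{\link{contrastStats}} tables.
#' @param metric which log2 change to extract ("mRNA", "RPF" or "TE").
#' @return named list per contrast: list(values, nDropped, stats =
#'   \code{\link{boxplotStats}} summary).
#' @export
setResponse <- function(set, statsTables, metric = c("mRNA", "RPF", "TE")) {
    metric <- match.arg(metric)
    if (!length(geneIds(set))) stop("gene set is empty")
    col <- switch(metric, mRNA = "log2_dmrna", RPF = "log2_drpf",
                  TE = "log2_dte")
    lapply(statsTables, function(st) {
        v <- st[[col]][match(geneIds(set), st$gene_id)]
        dropped <- sum(is.na(v))
        v <- v[!is.na(v)]
        list(values = v, nDropped = dropped,
             stats = if (length(v)) boxplotStats(v) else NULL)
    })
}

#' Pre-filter and partition genes for clustering display
#'
#' Drops genes missing a value in any mutant column or with |log2 change| >
#' 4 anywhere, then partitions the rest into an inner set (all values within
#' [-2, 2]) and an outer set (any value outside).
#'
#' @param dteTable data.frame with gene_id and one log2-change column per
#'   mutant.
#' @return list(dropped, inner, outer) of gene-id vectors.
#' @export
clusteringPrefilter <- function(dteTable) {
    if (!"gene_id" %in% names(dteTable))
        stop("dteTable needs a gene_id column")
    m <- as.matrix(dteTable[setdiff(names(dteTable), "gene_id")])
    if (!ncol(m)) stop("dteTable needs at least one value column")
    drop <- apply(m, 1, function(r) any(!is.finite(r)) || any(abs(r) > 4))
    innerMask <- !drop & apply(m, 1, function(r) all(abs(r) <= 2))
    outerMask <- !drop & !innerMask
    list(dropped = dteTable$gene_id[drop],
         inner = dteTable$gene_id[innerMask],
         outer = dteTable$gene_id[outerMask])
}
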