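# Set-level and covariate statistics: hypergeometric overlap p-values,
# notched box-plot summaries, pentile binning against a covariate, Pearson
# correlation, and codon-optimality (sTAI) binning.

#' Hypergeometric overlap test (enrichment, upper tail)
#'
#' p = P(X >= nOverlap) for X ~ Hypergeometric(N = nUniverse, K = nB,
#' draws = nA): the probability of drawing at least the observed overlap
#' when set A is sampled from the universe without replacement. The tail
#' includes the observed overlap, so nOverlap = 0 gives p = 1.
#'
#' @param nUniverse,nA,nB,nOverlap counts; must satisfy
#'   nOverlap <= min(nA, nB), nA, nB <= nUniverse and
#'   nOverlap >= nA + nB - nUniverse.
#' @return list(nUniverse, nA, nB, nOverlap, p) of class "OverlapResult".
#' @examples
#' hypergeometricOverlap(10, 4, 5, 3)$p  # 55/210
#' @export
hypergeometricOverlap <- function(nUniverse, nA, nB, nOverlap) {
    if (nA > nUniverse || nB > nUniverse)
        stop("set sizes cannot exceed the universe")
    if (nOverlap > min(nA, nB) || nOverlap < max(0, nA + nB - nUniverse))
        stop("impossible overlap count")
    p <- phyper(nOverlap - 1, nB, nUniverse - nB, nA, lower.tail = FALSE)
    structure(list(nUniverse = nUniverse, nA = nA, nB = nB,
                   nOverlap = nOverlap, p = p),
              class = "OverlapResult")
}

#' Notched box-plot statistics
#'
#' Median, quartiles (linear interpolation between order statistics,
#' \code{quantile} type 7), whiskers at the most extreme points within
#' 1.5 IQR of the quartiles, and McGill notches at
#' median +/- 1.58 IQR / sqrt(n) — the de facto standard notch whose
#' non-overlap indicates differing medians with roughly 95% confidence.
#' Notches require n >= 2 (NA otherwise). Order-invariant.
#'
#' @param values numeric, n >= 1.
#' @return list(median, q1, q3, notchLow, notchHigh, whiskerLow,
#'   whiskerHigh, n) of class "BoxplotStats".
#' @export
boxplotStats <- function(values) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 1) stop("empty input")
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lowFence <- q[1] - 1.5 * iqr
    highFence <- q[3] + 1.5 * iqr
    half <- if (n >= 2) 1.58 * iqr / sqrt(n) else NA_real_
    structure(list(median = q[2], q1 = q[1], q3 = q[3],
                   notchLow = q[2] - half, notchHigh = q[2] + half,
                   whiskerLow = min(values[values >= lowFence]),
                   whiskerHigh = max(values[values <= highFence]),
                   n = n),
              class = "BoxplotStats")
}

#' Are two medians distinguishable by their notches?
#'
#' TRUE when the notch intervals do not overlap (roughly 95% confidence that
#' the medians differ). Symmetric in its arguments.
#'
#' @param a,b "BoxplotStats" from \code{\link{boxplotStats}} (n >= 2 each).
#' @return logical.
#' @export
notchOverlap <- function(a, b) {
    if (is.na(a$notchLow) || is.na(b$notchLow))
        stop("notches require n >= 2 in both groups")
    a$notchLow > b$notchHigh || b$notchLow > a$notchHigh
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with p from the t transform on n - 2 degrees of freedom.
#' Non-finite pairs are removed first; zero variance in either vector yields
#' NA with a warning (undefined correlation).
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list(r, p, n).
#' @export
pearsonCor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) stop("need at least 3 finite pairs")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("zero variance: correlation undefined")
        return(list(r = NA_real_, p = NA_real_, n = n))
    }
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Pentile (equal-size quantile bin) analysis of a response vs a covariate
#'
#' Genes with both values are sorted by the covariate ascending (ties broken
#' by gene id, so binning is deterministic) and split into k nearly equal
#' bins, any remainder going to the lowest bins; each bin's response is
#' summarized with \code{\link{boxplotStats}} and the overall Pearson
#' correlation is reported.
#'
#' @param covariate,response named numeric vectors (names = gene ids) or
#'   unnamed equal-length vectors.
#' @param k number of bins (default 5 pentiles; >= 2).
#' @return list(binAssignments, binSizes, perBinStats, binCovariateMedians,
#'   pearsonR, pearsonP, n) of class "PentileBinning".
#' @export
pentileBinning <- function(covariate, response, k = 5L) {
    if (k < 2) stop("k must be >= 2")
    if (is.null(names(covariate)))
        names(covariate) <- names(response) <- as.character(seq_along(covariate))
    common <- intersect(names(covariate)[is.finite(covariate)],
                        names(response)[is.finite(response)])
    n <- length(common)
    if (n < k) stop("need at least k genes with both values")
    cv <- covariate[common]
    ord <- common[order(cv, common)]
    base <- n %/% k; rem <- n %% k
    sizes <- base + as.integer(seq_len(k) <= rem)
    bin <- rep(seq_len(k), times = sizes)
    names(bin) <- ord
    perBin <- lapply(seq_len(k), function(b) boxplotStats(response[ord[bin == b]]))
    covMed <- vapply(seq_len(k), function(b) median(covariate[ord[bin == b]]),
                     numeric(1))
    pc <- pearsonCor(covariate[common], response[common])
    structure(list(binAssignments = bin, binSizes = sizes,
                   perBinStats = perBin, binCovariateMedians = covMed,
                   pearsonR = pc$r, pearsonP = pc$p, n = n),
              class = "PentileBinning")
}

#' Bin a response by fixed sTAI (codon-optimality) intervals
#'
#' Genes are assigned to half-open bins [e_i, e_{i+1}) defined by ascending
#' edges; each bin's response gets box-plot statistics and its median
#' covariate is reported. Genes outside all bins are counted, not silently
#' dropped.
#'
#' @param stai,response named numeric vectors (names = gene ids).
#' @param binEdges ascending break points.
#' @return list(perBinStats, binCovariateMedians, binSizes, nOutside) of
#'   class "StaiBinning".
#' @export
staiBinning <- function(stai, response, binEdges) {
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly ascending")
    if (is.null(names(stai)))
        names(stai) <- names(response) <- as.character(seq_along(stai))
    common <- intersect(names(stai)[is.finite(stai)],
                        names(response)[is.finite(response)])
    s <- stai[common]; r <- response[common]
    nb <- length(binEdges) - 1L
    idx <- findInterval(s, binEdges, rightmost.closed = FALSE)
    inRange <- idx >= 1 & idx <= nb & s < binEdges[nb + 1L]
    perBin <- vector("list", nb)
    med <- sizes <- rep(NA_real_, nb)
    for (b in seq_len(nb)) {
        sel <- inRange & idx == b
        sizes[b] <- sum(sel)
        if (sizes[b] > 0) {
            perBin[[b]] <- boxplotStats(r[sel])
            med[b] <- median(s[sel])
        }
    }
    structure(list(perBinStats = perBin, binCovariateMedians = med,
                   binSizes = sizes, nOutside = sum(!inRange)),
              class = "StaiBinning")
}
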