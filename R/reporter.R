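# Tethered-function reporter calculus: relative qPCR abundance, normalized
# protein, replicate summaries, repression ratios with propagated SEM,
# replicate-paired delta-TE, and significance labelling.

#' Relative mRNA abundance from Ct triplicates
#'
#' The reporter/reference abundance ratio is the ratio of the mean
#' 2^-Ct values — the transform is applied before averaging, so
#' mean(2^-Ct_reporter) / mean(2^-Ct_reference), not 2^-(mean delta-Ct).
#' The result is invariant to adding a constant to all Ct values.
#'
#' @param ctReporter,ctReference numeric Ct technical replicates (finite).
#' @return positive scalar relative abundance.
#' @examples
#' relativeAbundance(c(11, 11, 11), c(10, 10, 10))  # 0.5
#' @export
relativeAbundance <- function(ctReporter, ctReference) {
    if (length(ctReporter) == 0 || length(ctReference) == 0)
        stop("Ct triplicates must be non-empty")
    if (any(!is.finite(ctReporter)) || any(!is.finite(ctReference)))
        stop("Ct values must be finite")
    mean(2^-ctReporter) / mean(2^-ctReference)
}

#' Loading-control normalization of protein signal
#'
#' @param proteinSignal,loadingSignal densitometry signals (same units);
#'   elementwise ratio, order preserved.
#' @return proteinSignal / loadingSignal.
#' @export
normalizeProtein <- function(proteinSignal, loadingSignal) {
    if (any(!is.finite(loadingSignal)) || any(loadingSignal <= 0))
        stop("loading signal must be positive and finite")
    proteinSignal / loadingSignal
}

#' Replicate summary: mean, sd, SEM
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and standard
#' error of the mean sd/sqrt(n). At least two replicates are required, since
#' the SEM feeds error propagation downstream.
#'
#' @param values numeric replicate measurements (n >= 2).
#' @return list(mean, sd, sem, n) of class "ExpressionSummary".
#' @export
summarizeExpression <- function(values) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 2) stop("need at least 2 replicates to summarize")
    s <- sd(values)
    structure(list(mean = mean(values), sd = s, sem = s / sqrt(n), n = n),
              class = "ExpressionSummary")
}

#' Ratio of two means with propagated SEM
#'
#' ratio = X/Y with propagated standard error
#' (X/Y) * sqrt((SE_x/X)^2 + (SE_y/Y)^2), the first-order delta-method
#' propagation through relative SEMs.
#'
#' @param numerator,denominator summaries from
#'   \code{\link{summarizeExpression}} (or any list with mean, sem, n).
#' @return a \linkS4class{RatioWithError}.
#' @examples
#' x <- summarizeExpression(c(1.8, 2.0, 2.2))
#' y <- summarizeExpression(c(3.9, 4.0, 4.1))
#' ratioOfMeans(x, y)
#' @export
ratioOfMeans <- function(numerator, denominator) {
    X <- numerator$mean; Y <- denominator$mean
    if (!is.finite(Y) || Y <= 0) stop("denominator mean must be positive")
    if (!is.finite(X) || X <= 0) stop("numerator mean must be positive")
    r <- X / Y
    sem <- r * sqrt((numerator$sem / X)^2 + (denominator$sem / Y)^2)
    new("RatioWithError", ratio = r, sem = sem,
        nNum = as.integer(numerator$n), nDen = as.integer(denominator$n))
}

#' Replicate-paired change in translational efficiency
#'
#' For each pair of treated/control biological replicates, the protein and
#' mRNA repression ratios are formed and their quotient is the per-pair
#' delta-TE: (protein_t/protein_c) / (mrna_t/mrna_c). Equal repression of
#' protein and mRNA gives delta-TE = 1. Pairs are matched by position in the
#' input vectors (replicate index in input order); supply \code{pairing} to
#' permute the control assignment.
#'
#' @param proteinTreated,proteinControl,mrnaTreated,mrnaControl equal-length
#'   numeric vectors of per-replicate normalized values (>= 3 pairs).
#' @param pairing optional permutation of control indices.
#' @return list(perPair, mean, sem, n) of class "PairedTEChange".
#' @export
pairedDeltaTE <- function(proteinTreated, proteinControl,
                          mrnaTreated, mrnaControl,
                          pairing = seq_along(proteinControl)) {
    n <- length(proteinTreated)
    if (n < 3) stop("need at least 3 replicate pairs for delta-TE")
    if (length(proteinControl) != n || length(mrnaTreated) != n ||
        length(mrnaControl) != n)
        stop("all four replicate vectors must have equal length")
    pc <- proteinControl[pairing]; mc <- mrnaControl[pairing]
    if (any(pc <= 0) || any(mc <= 0))
        stop("control values must be positive")
    dte <- (proteinTreated / pc) / (mrnaTreated / mc)
    structure(list(perPair = dte, mean = mean(dte),
                   sem = sd(dte) / sqrt(n), n = n),
              class = "PairedTEChange")
}

#' Unpaired two-sample t-test with significance label
#'
#' Classical pooled-variance Student t-test (the study's stated test), with
#' Welch's unequal-variance form behind \code{welch = TRUE}. Two-sided.
#' Degenerate input (zero variance in both groups) yields t = 0, p = 1 when
#' the means agree and p = 0 otherwise, by convention.
#'
#' @param a,b numeric groups, each n >= 2.
#' @param welch use Welch's correction instead of pooled variance.
#' @return list(t, df, p, label) of class "TTestResult".
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 values")
    if (sd(a) == 0 && sd(b) == 0) {
        if (mean(a) == mean(b))
            res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
        else
            res <- list(t = sign(mean(a) - mean(b)) * Inf,
                        df = length(a) + length(b) - 2, p = 0)
    } else {
        tt <- t.test(a, b, var.equal = !welch)
        res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                    p = unname(tt$p.value))
    }
    res$label <- significanceLabel(res$p)
    class(res) <- "TTestResult"
    res
}

#' Significance label from a p-value
#'
#' "**" for p < 0.01, "*" for p < 0.05, otherwise "n.s." (strict
#' inequalities, so p = 0.05 is "n.s.").
#'
#' @param p probability (vectorized).
#' @return character label(s).
#' @export
significanceLabel <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p must lie in [0, 1]")
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))
}

#' Full reporter-experiment analysis
#'
#' From a raw reporter sample table (one row per strain x construct x
#' biological replicate), computes per replicate the loading-normalized
#' protein (GFP/LC) and qPCR relative abundance, summarizes each construct,
#' and for each strain forms treated/control repression ratios with
#' propagated SEM, the replicate-paired delta-TE, and unpaired t-tests
#' comparing treated against control replicate values.
#'
#' @param samples data.frame with columns strain, construct, bioreplicate,
#'   protein_signal, loading_signal, ct_reporter_1..k, ct_reference_1..k
#'   (see \code{\link{simulateReporterExperiment}} /
#'   \code{\link{readReporterSamples}}).
#' @param treated,control construct labels (tethered fusion vs MS2-only
#'   control).
#' @return data.frame, one row per strain: repression ratios and propagated
#'   SEMs for protein and mRNA, mean delta-TE and SEM, t-test p-values and
#'   significance labels.
#' @export
analyzeReporter <- function(samples, treated, control) {
    need <- c("strain", "construct", "bioreplicate",
              "protein_signal", "loading_signal")
    if (!all(need %in% names(samples)))
        stop("missing reporter sample columns: ",
             paste(setdiff(need, names(samples)), collapse = ", "))
    repCols <- grep("^ct_reporter_", names(samples), value = TRUE)
    refCols <- grep("^ct_reference_", names(samples), value = TRUE)
    if (!length(repCols) || !length(refCols))
        stop("missing ct_reporter_*/ct_reference_* columns")

    samples$gfp_lc <- normalizeProtein(samples$protein_signal,
                                       samples$loading_signal)
    samples$rel_mrna <- vapply(seq_len(nrow(samples)), function(i)
        relativeAbundance(as.numeric(samples[i, repCols]),
                          as.numeric(samples[i, refCols])), numeric(1))

    out <- lapply(split(samples, samples$strain), function(ss) {
        tr <- ss[ss$construct == treated, ]
        ct <- ss[ss$construct == control, ]
        tr <- tr[order(tr$bioreplicate), ]
        ct <- ct[order(ct$bioreplicate), ]
        if (nrow(tr) < 2 || nrow(ct) < 2)
            stop(sprintf("strain %s: need >= 2 replicates of both constructs",
                         ss$strain[1]))
        protRatio <- ratioOfMeans(summarizeExpression(tr$gfp_lc),
                                  summarizeExpression(ct$gfp_lc))
        mrnaRatio <- ratioOfMeans(summarizeExpression(tr$rel_mrna),
                                  summarizeExpression(ct$rel_mrna))
        nPair <- min(nrow(tr), nrow(ct))
        dte <- pairedDeltaTE(tr$gfp_lc[seq_len(nPair)], ct$gfp_lc[seq_len(nPair)],
                             tr$rel_mrna[seq_len(nPair)], ct$rel_mrna[seq_len(nPair)])
        tProt <- unpairedTTest(tr$gfp_lc, ct$gfp_lc)
        tMrna <- unpairedTTest(tr$rel_mrna, ct$rel_mrna)
        data.frame(strain = ss$strain[1],
                   n_treated = nrow(tr), n_control = nrow(ct),
                   protein_ratio = ratioValue(protRatio),
                   protein_sem = propagatedSem(protRatio),
                   mrna_ratio = ratioValue(mrnaRatio),
                   mrna_sem = propagatedSem(mrnaRatio),
                   dte_mean = dte$mean, dte_sem = dte$sem,
                   p_protein = tProt$p, label_protein = tProt$label,
                   p_mrna = tMrna$p, label_mrna = tMrna$label,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
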