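# Polysome gradient analysis: per-fraction qPCR signals to percentage
# distributions, and replicate-level per-fraction comparisons between
# conditions.

#' Fraction distribution as percentages of total gradient signal
#'
#' percentage_i = 100 * signal_i / sum(signal); percentages sum to 100 and
#' are invariant to scaling all signals by a positive constant.
#'
#' @param signal non-negative per-fraction signals (mean 2^-Ct values),
#'   ordered top to bottom of the gradient.
#' @return numeric percentages, same length and order.
#' @export
fractionDistribution <- function(signal) {
    if (length(signal) < 2) stop("need at least 2 fractions")
    if (any(!is.finite(signal)) || any(signal < 0))
        stop("signals must be finite and non-negative")
    tot <- sum(signal)
    if (tot <= 0) stop("total gradient signal must be positive")
    100 * signal / tot
}

#' Per-replicate gradient distributions from a long-format table
#'
#' Accepts either a \code{signal} column or qPCR technical-replicate columns
#' \code{ct_1..k} (averaged as mean 2^-Ct per fraction), then converts each
#' condition x replicate profile into percentages of total signal.
#'
#' @param gradient data.frame(condition, bioreplicate, fraction, signal) or
#'   (condition, bioreplicate, fraction, ct_1..k).
#' @return the input with columns \code{signal} and \code{percent} added,
#'   ordered by condition, bioreplicate, fraction.
#' @export
gradientDistributions <- function(gradient) {
    need <- c("condition", "bioreplicate", "fraction")
    if (!all(need %in% names(gradient)))
        stop("gradient table must have columns: ", paste(need, collapse = ", "))
    ctCols <- grep("^ct_[0-9]+$", names(gradient), value = TRUE)
    if (!"signal" %in% names(gradient)) {
        if (!length(ctCols))
            stop("gradient table needs a 'signal' column or ct_1..k columns")
        gradient$signal <- rowMeans(2^-as.matrix(gradient[ctCols]))
    }
    parts <- split(gradient, list(gradient$condition, gradient$bioreplicate),
                   drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(p) {
        p <- p[order(p$fraction), ]
        p$percent <- fractionDistribution(p$signal)
        p
    }))
    rownames(out) <- NULL
    out[order(out$condition, out$bioreplicate, out$fraction), ]
}

#' Compare one gradient fraction between two conditions
#'
#' Unpaired Student t-test on the percentage of total signal in the given
#' fraction across replicate profiles. Symmetric in the two groups up to the
#' sign of t.
#'
#' @param profilesA,profilesB replicate-by-fraction matrices of percentages
#'   (rows = replicates), with equal fraction counts.
#' @param fraction fraction index to test.
#' @return a "TTestResult" list (t, df, p, label).
#' @export
compareFraction <- function(profilesA, profilesB, fraction) {
    profilesA <- as.matrix(profilesA); profilesB <- as.matrix(profilesB)
    if (ncol(profilesA) != ncol(profilesB))
        stop("fraction counts differ between the two groups")
    if (fraction < 1 || fraction > ncol(profilesA))
        stop("fraction index out of range")
    unpairedTTest(profilesA[, fraction], profilesB[, fraction])
}

#' Per-fraction tests across a whole gradient
#'
#' Runs \code{\link{compareFraction}} for every fraction. Raw per-fraction
#' p-values match the study's convention; a Benjamini-Hochberg adjusted
#' column is emitted alongside for honesty about multiplicity.
#'
#' @param profilesA,profilesB replicate-by-fraction percentage matrices.
#' @return data.frame(fraction, t, p, label, fdr).
#' @export
perFractionTests <- function(profilesA, profilesB) {
    profilesA <- as.matrix(profilesA); profilesB <- as.matrix(profilesB)
    if (ncol(profilesA) != ncol(profilesB))
        stop("fraction counts differ between the two groups")
    res <- lapply(seq_len(ncol(profilesA)), function(f)
        compareFraction(profilesA, profilesB, f))
    data.frame(fraction = seq_len(ncol(profilesA)),
               t = vapply(res, `[[`, numeric(1), "t"),
               p = vapply(res, `[[`, numeric(1), "p"),
               label = vapply(res, `[[`, character(1), "label"),
               fdr = p.adjust(vapply(res, `[[`, numeric(1), "p"), "BH"),
               stringsAsFactors = FALSE)
}

#' Reshape long-format distributions to replicate-by-fraction matrices
#'
#' @param distributions output of \code{\link{gradientDistributions}}.
#' @param condition condition label to extract.
#' @return matrix with one row per bioreplicate, one column per fraction.
#' @export
profileMatrix <- function(distributions, condition) {
    d <- distributions[distributions$condition == condition, ]
    if (!nrow(d)) stop("no rows for condition: ", condition)
    reps <- sort(unique(d$bioreplicate))
    fracs <- sort(unique(d$fraction))
    m <- matrix(NA_real_, length(reps), length(fracs),
                dimnames = list(reps, fracs))
    for (i in seq_len(nrow(d)))
        m[as.character(d$bioreplicate[i]), as.character(d$fraction[i])] <- d$percent[i]
    m
}
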