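# First-order mRNA decay kinetics from promoter-shutoff time courses:
# percent-remaining normalization, log-linear initial-rate fits, half-lives,
# and group comparison.

#' Normalize a shutoff time course to percent remaining
#'
#' Each relative-abundance value is divided by the value at t = 0 and
#' multiplied by 100, so the series starts at exactly 100. Idempotent, and
#' invariant to scaling the raw abundances by any positive constant.
#'
#' @param times numeric times in minutes (must include 0).
#' @param values relative abundances at those times (value at 0 must be > 0).
#' @return data.frame(time_min, percent_remaining), ordered by time.
#' @export
percentRemaining <- function(times, values) {
    stopifnot(length(times) == length(values))
    o <- order(times)
    times <- times[o]; values <- values[o]
    i0 <- which(times == 0)
    if (length(i0) == 0) stop("time course must include a t = 0 point")
    v0 <- values[i0[1]]
    if (!is.finite(v0) || v0 <= 0) stop("value at t = 0 must be positive")
    data.frame(time_min = times, percent_remaining = values / v0 * 100)
}

#' Fit the initial decay rate and half-life
#'
#' Ordinary least squares of ln(percent remaining) against time over a
#' window of early time points (default all t <= 10 min, the first five
#' post-shift samples of the standard 2/4/6/8/10/15/20/30/40/60-min
#' schedule; the t = 0 point is included since it is exact by construction).
#' The decay rate is minus the slope and the half-life is
#' \code{halfLifeConstant / k} with constant 0.693 by default (use
#' \code{log(2)} for the exact natural-log value). Non-positive values in
#' the window are dropped with a warning (their log is undefined); a fit
#' with k <= 0 is flagged invalid.
#'
#' @param times,percent time points (min) and percent-remaining values, e.g.
#'   the columns of \code{\link{percentRemaining}} output.
#' @param window numeric (first, last): time bounds of the fit, inclusive.
#' @param halfLifeConstant numerator of the half-life formula.
#' @return a \linkS4class{HalfLife}.
#' @examples
#' t <- c(0, 2, 4, 6, 8, 10)
#' fitInitialDecay(t, 100 * exp(-0.2475 * t))  # t1/2 = 2.8 min
#' @export
fitInitialDecay <- function(times, percent, window = c(0, 10),
                            halfLifeConstant = 0.693) {
    stopifnot(length(times) == length(percent), length(window) == 2)
    sel <- times >= window[1] & times <= window[2]
    times <- times[sel]; percent <- percent[sel]
    bad <- !is.finite(percent) | percent <= 0
    if (any(bad)) {
        warning(sprintf("dropping %d non-positive point(s) from the fit window", sum(bad)))
        times <- times[!bad]; percent <- percent[!bad]
    }
    if (length(times) < 3)
        stop("need at least 3 positive points in the fit window")
    fit <- lm(log(percent) ~ times)
    k <- -unname(coef(fit)[2])
    y <- log(percent)
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot > 0) 1 - sum(fit$residuals^2) / ssTot else NA_real_
    valid <- is.finite(k) && k > 0
    new("HalfLife", k = k,
        tHalf = if (valid) halfLifeConstant / k else NA_real_,
        halfLifeConstant = halfLifeConstant, window = as.numeric(window),
        rSquared = r2, nPoints = length(times), valid = valid)
}

#' Fit half-lives for every replicate in a decay table
#'
#' @param decay data.frame(bioreplicate, time_min, relative_abundance), as
#'   written by the simulator or read with \code{\link{readDecayTable}}.
#' @param window,halfLifeConstant passed to \code{\link{fitInitialDecay}}.
#' @return data.frame(bioreplicate, k, t_half_min, r_squared, window_start,
#'   window_end, valid).
#' @export
fitDecayTable <- function(decay, window = c(0, 10), halfLifeConstant = 0.693) {
    need <- c("bioreplicate", "time_min", "relative_abundance")
    if (!all(need %in% names(decay)))
        stop("decay table must have columns: ", paste(need, collapse = ", "))
    out <- lapply(split(decay, decay$bioreplicate), function(d) {
        pr <- percentRemaining(d$time_min, d$relative_abundance)
        hl <- fitInitialDecay(pr$time_min, pr$percent_remaining,
                              window = window,
                              halfLifeConstant = halfLifeConstant)
        data.frame(bioreplicate = d$bioreplicate[1], k = decayRate(hl),
                   t_half_min = halfLife(hl), r_squared = hl@rSquared,
                   window_start = window[1], window_end = window[2],
                   valid = hl@valid, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Compare half-lives between two groups
#'
#' Unpaired Student t-test on per-replicate half-life estimates; invalid
#' estimates (k <= 0) are excluded first.
#'
#' @param groupA,groupB numeric half-life vectors, lists of
#'   \linkS4class{HalfLife} objects, or \code{\link{fitDecayTable}} outputs.
#' @param welch passed to \code{\link{unpairedTTest}}.
#' @return a "TTestResult" list (t, df, p, label).
#' @export
compareHalfLives <- function(groupA, groupB, welch = FALSE) {
    extract <- function(g) {
        if (is.data.frame(g)) return(g$t_half_min[g$valid])
        if (is.list(g) && all(vapply(g, is, logical(1), "HalfLife")))
            return(vapply(Filter(function(h) h@valid, g), halfLife, numeric(1)))
        g[is.finite(g) & g > 0]
    }
    a <- extract(groupA); b <- extract(groupB)
    if (length(a) < 2 || length(b) < 2)
        stop("need at least 2 valid half-life estimates per group")
    unpairedTTest(a, b, welch = welch)
}
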