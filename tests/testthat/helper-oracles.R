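# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# textbook pooled-variance two-sample t-test
oracleStudentT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force upper-tail hypergeometric by enumeration over overlap outcomes
oracleHyper <- function(N, nA, nB, k) {
    lo <- max(0, nA + nB - N); hi <- min(nA, nB)
    if (k > hi || k < lo) stop("impossible overlap")
    num <- sum(vapply(k:hi, function(i) choose(nB, i) * choose(N - nB, nA - i),
                      numeric(1)))
    num / choose(N, nA)
}

# Benjamini-Hochberg step-up from the definition
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

# two-pass sample variance
oracleVar <- function(x) sum((x - mean(x))^2) / (length(x) - 1)

# direct covariance-formula Pearson r
oraclePearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small no-noise reporter configuration
zeroNoiseConfig <- function(seed = 1L)
    simConfig(seed = seed, nGenes = 200L, measurementCv = 0, ctSd = 0,
              decayNoiseCv = 0)
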