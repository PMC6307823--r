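# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, emulating the experimental designs
# of the tethering/profiling study: reporter densitometry + qPCR triplicates,
# promoter-shutoff decay series, polysome gradient fractions, and paired
# RPF/RNA count matrices across a WT / scd6d / dhh1d / dcp2d (+ doubles)
# strain panel.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module with validation.
#' Defaults describe the emulated study: two biological replicates per
#' genotype, qPCR technical triplicates, ~6,000 genes with negative-binomial
#' counts (variance mu + mu^2/dispersion), 10% of genes carrying a 2-fold
#' mRNA-abundance effect in the mRNA-effect genotype and 10% a 0.5x TE effect
#' in the TE-effect genotype, with effects of scd6d/dhh1d nulled on a dcp2d
#' background (epistasis) by default.
#'
#' @param seed integer RNG seed; identical configs give identical outputs.
#' @param nGenes number of genes for count simulation (>= 100).
#' @param genotypes strain panel labels; double mutants are written
#'   "dcp2d_scd6d" style, the underscore separating the deletions.
#' @param nBioreps biological replicates per genotype for count matrices.
#' @param nTechreps qPCR technical replicates.
#' @param baseMeanRange range of per-gene base RNA mean counts (log-uniform).
#' @param dispersion NB size parameter (var = mu + mu^2/dispersion);
#'   \code{Inf} gives the Poisson limit.
#' @param fracMrnaUp,mrnaEffectFold,mrnaEffectGenotype fraction of genes,
#'   fold, and single-mutant genotype carrying the mRNA-abundance effect.
#' @param fracTeDown,teEffectFold,teEffectGenotype same for the TE effect.
#' @param epistasis if TRUE (default), scd6d/dhh1d effects are nulled in
#'   genotypes that also carry dcp2d.
#' @param measurementCv lognormal coefficient of variation of reporter
#'   protein/loading signals.
#' @param ctBaseline,ctSd qPCR model: Ct = ctBaseline - log2(abundance) +
#'   Normal(0, ctSd).
#' @param decayK default per-minute decay rate for shutoff series.
#' @param decayNoiseCv multiplicative noise on decay measurements.
#' @param timepointsMin sampling times in minutes, strictly increasing,
#'   starting at 0 (default: the study's 0/2/4/6/8/10/15/20/30/40/60 min
#'   schedule).
#' @param ripCorrelation target Pearson correlation between simulated RIP-seq
#'   enrichment and log2 of the true TE effect.
#' @param staiMean,staiConcentration Beta-distribution parameters for
#'   simulated sTAI codon-optimality scores (mean 0.35, the yeast genome
#'   average).
#' @param libSizeSd sd of lognormal per-sample library-size factors.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 6000L,
                      genotypes = c("WT", "scd6d", "dhh1d", "dcp2d",
                                    "dcp2d_scd6d", "dcp2d_dhh1d"),
                      nBioreps = 2L,
                      nTechreps = 3L,
                      baseMeanRange = c(100, 1000),
                      dispersion = 10,
                      fracMrnaUp = 0.1,
                      mrnaEffectFold = 2,
                      mrnaEffectGenotype = "scd6d",
                      fracTeDown = 0.1,
                      teEffectFold = 0.5,
                      teEffectGenotype = "dhh1d",
                      epistasis = TRUE,
                      measurementCv = 0.1,
                      ctBaseline = 20,
                      ctSd = 0.15,
                      decayK = 0.2475,
                      decayNoiseCv = 0.05,
                      timepointsMin = c(0, 2, 4, 6, 8, 10, 15, 20, 30, 40, 60),
                      ripCorrelation = 0.2,
                      staiMean = 0.35,
                      staiConcentration = 25,
                      libSizeSd = 0.1) {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                genotypes = genotypes, nBioreps = as.integer(nBioreps),
                nTechreps = as.integer(nTechreps),
                baseMeanRange = baseMeanRange, dispersion = dispersion,
                fracMrnaUp = fracMrnaUp, mrnaEffectFold = mrnaEffectFold,
                mrnaEffectGenotype = mrnaEffectGenotype,
                fracTeDown = fracTeDown, teEffectFold = teEffectFold,
                teEffectGenotype = teEffectGenotype, epistasis = epistasis,
                measurementCv = measurementCv, ctBaseline = ctBaseline,
                ctSd = ctSd, decayK = decayK, decayNoiseCv = decayNoiseCv,
                timepointsMin = timepointsMin,
                ripCorrelation = ripCorrelation, staiMean = staiMean,
                staiConcentration = staiConcentration, libSizeSd = libSizeSd)
    validateSimConfig(cfg)
    class(cfg) <- "SimConfig"
    cfg
}

validateSimConfig <- function(cfg) {
    stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L, !is.na(cfg$seed))
    if (abs(cfg$seed) >= 2^31) stop("seed must fit a 32-bit integer")
    for (f in c("fracMrnaUp", "fracTeDown"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop(sprintf("%s must lie in [0, 1]", f))
    for (f in c("mrnaEffectFold", "teEffectFold", "dispersion", "decayK"))
        if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
            stop(sprintf("%s must be a positive real", f))
    tp <- cfg$timepointsMin
    if (tp[1] != 0 || any(diff(tp) <= 0))
        stop("timepointsMin must be strictly increasing with first element 0")
    if (abs(cfg$ripCorrelation) >= 1)
        stop("ripCorrelation must satisfy |r| < 1")
    if (any(cfg$baseMeanRange <= 0) || cfg$baseMeanRange[2] < cfg$baseMeanRange[1])
        stop("baseMeanRange must be a positive, ordered pair")
    invisible(TRUE)
}

# lognormal draws with exact mean m and coefficient of variation cv
rlnormCv <- function(n, m, cv) {
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

deletionsOf <- function(genotype) {
    if (genotype == "WT") character() else strsplit(genotype, "_", fixed = TRUE)[[1]]
}

# does the single-mutant effect `effGeno` express in compound genotype `geno`?
effectApplies <- function(geno, effGeno, epistasis) {
    dels <- deletionsOf(geno)
    if (!(effGeno %in% dels)) return(FALSE)
    !(epistasis && "dcp2d" %in% dels && effGeno != "dcp2d")
}

#' Simulate a tethered-function reporter experiment
#'
#' Generates one table row per strain x construct x biological replicate with
#' protein densitometry, loading-control signal, and qPCR Ct technical
#' triplicates for reporter and reference transcripts. Protein and loading
#' signals are lognormal around the construct means with CV
#' \code{config$measurementCv}; Ct values follow
#' Ct = ctBaseline - log2(abundance) + Normal(0, ctSd), so downstream 2^-Ct
#' arithmetic recovers relative abundance. At zero noise the downstream
#' repression ratios equal the construct effects exactly.
#'
#' @param config a \code{\link{simConfig}}.
#' @param constructEffects named list mapping construct label to
#'   c(protein = fold, mrna = fold); must include a reference construct with
#'   folds (1, 1).
#' @param strains strain labels to simulate (effects identical across strains
#'   unless \code{strainModifiers} scales them).
#' @param nBioreps biological replicates per strain x construct (the study
#'   used three or more for reporter assays).
#' @param strainModifiers optional named list mapping strain to
#'   c(protein = fold, mrna = fold) multipliers applied on top of the
#'   construct effect for non-reference constructs (models genotype-dependent
#'   repression).
#' @return data.frame with columns strain, construct, bioreplicate,
#'   protein_signal, loading_signal, ct_reporter_1..k, ct_reference_1..k.
#' @export
simulateReporterExperiment <- function(config, constructEffects,
                                       strains = "WT", nBioreps = 3L,
                                       strainModifiers = NULL) {
    stopifnot(inherits(config, "SimConfig"), length(constructEffects) >= 1)
    eff <- lapply(constructEffects, function(e) {
        e <- unlist(e)
        if (length(e) != 2 || any(!is.finite(e)) || any(e <= 0))
            stop("construct effects must be two positive folds (protein, mrna)")
        setNames(as.numeric(e), c("protein", "mrna"))
    })
    isRef <- vapply(eff, function(e) all(e == 1), logical(1))
    if (!any(isRef))
        stop("constructEffects must include a reference construct with folds (1, 1)")
    set.seed(config$seed)
    k <- config$nTechreps
    rows <- list()
    for (st in strains) for (cn in names(eff)) {
        e <- eff[[cn]]
        if (!is.null(strainModifiers) && !isRef[[cn]] && st %in% names(strainModifiers))
            e <- e * setNames(unlist(strainModifiers[[st]]), c("protein", "mrna"))
        for (br in seq_len(nBioreps)) {
            protein <- rlnormCv(1, e[["protein"]], config$measurementCv)
            loading <- rlnormCv(1, 1, config$measurementCv)
            ctRep <- config$ctBaseline - log2(e[["mrna"]]) + rnorm(k, 0, config$ctSd)
            ctRef <- config$ctBaseline + rnorm(k, 0, config$ctSd)
            row <- data.frame(strain = st, construct = cn, bioreplicate = br,
                              protein_signal = protein,
                              loading_signal = loading,
                              stringsAsFactors = FALSE)
            for (j in seq_len(k)) row[[paste0("ct_reporter_", j)]] <- ctRep[j]
            for (j in seq_len(k)) row[[paste0("ct_reference_", j)]] <- ctRef[j]
            rows[[length(rows) + 1L]] <- row
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate promoter-shutoff decay time courses
#'
#' Relative abundance follows 100 * exp(-k t) * (1 + eps_t) with
#' eps_t ~ Normal(0, noiseCv); each replicate series is renormalized so its
#' t = 0 value is exactly 100.
#'
#' @param k per-minute decay rate (> 0).
#' @param config a \code{\link{simConfig}} (supplies timepoints, noise, seed).
#' @param nBioreps number of replicate series.
#' @param noiseCv overrides \code{config$decayNoiseCv} when given.
#' @return data.frame(bioreplicate, time_min, relative_abundance).
#' @export
simulateDecaySeries <- function(k, config, nBioreps = config$nBioreps,
                                noiseCv = config$decayNoiseCv) {
    if (!is.numeric(k) || length(k) != 1L || k <= 0)
        stop("decay rate k must be a positive scalar")
    set.seed(config$seed)
    tp <- config$timepointsMin
    out <- do.call(rbind, lapply(seq_len(nBioreps), function(br) {
        v <- 100 * exp(-k * tp) * (1 + rnorm(length(tp), 0, noiseCv))
        v <- pmax(v, 1e-6)
        v <- v / v[1] * 100
        data.frame(bioreplicate = br, time_min = tp, relative_abundance = v)
    }))
    rownames(out) <- NULL
    out
}

#' Simulate polysome gradient profiles
#'
#' A unimodal (Gaussian-shaped) signal across gradient fractions, peaking at
#' \code{peakFraction}; \code{spread = 0} puts all signal into the peak
#' fraction. Replicate profiles get multiplicative lognormal noise.
#'
#' @param peakFraction index of the peak (1..nFractions).
#' @param nFractions number of fractions, top to bottom (default 15).
#' @param spread Gaussian width in fraction units.
#' @param total total signal per profile.
#' @param cv per-fraction lognormal noise CV across replicates.
#' @param nBioreps number of replicate profiles.
#' @param condition condition label attached to the output.
#' @param seed RNG seed.
#' @return data.frame(condition, bioreplicate, fraction, signal).
#' @export
simulateGradient <- function(peakFraction, nFractions = 15L, spread = 1.5,
                             total = 1, cv = 0, nBioreps = 1L,
                             condition = "A", seed = 1L) {
    if (nFractions < 2) stop("nFractions must be >= 2")
    if (peakFraction < 1 || peakFraction > nFractions)
        stop("peakFraction must lie in 1..nFractions")
    if (total <= 0) stop("total must be positive")
    set.seed(seed)
    i <- seq_len(nFractions)
    shape <- if (spread <= 0) as.numeric(i == peakFraction)
             else exp(-0.5 * ((i - peakFraction) / spread)^2)
    out <- do.call(rbind, lapply(seq_len(nBioreps), function(br) {
        sig <- shape * rlnormCv(nFractions, 1, cv)
        sig <- sig / sum(sig) * total
        data.frame(condition = condition, bioreplicate = br,
                   fraction = i, signal = sig)
    }))
    rownames(out) <- NULL
    out
}

#' Simulate paired RPF/RNA count matrices with known ground truth
#'
#' RNA counts for gene g in sample s are negative binomial with mean
#' baseMean_g * mrnaFold_genotype(s) * librarySize_s and size
#' \code{config$dispersion} (Poisson when dispersion is infinite); RPF means
#' multiply the genotype-level RNA mean by baseTE_g * teFold_genotype(s) and
#' an independent RPF library-size factor. Double mutants carrying dcp2d have
#' scd6d/dhh1d effects nulled when \code{config$epistasis} is TRUE. WT folds
#' are identically 1.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{experiment}
#'   (a \linkS4class{TranslatomeExperiment}) and \code{truth} (data.frame:
#'   gene_id, base_rna_mean, base_te, mrna_fold_<genotype> and
#'   te_fold_<genotype> columns, rip_enrichment, stai).
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    if (config$nGenes < 100)
        stop("nGenes must be >= 100 (recovery statistics undefined below that)")
    set.seed(config$seed)
    n <- config$nGenes
    genes <- sprintf("gene%05d", seq_len(n))
    baseMean <- exp(runif(n, log(config$baseMeanRange[1]), log(config$baseMeanRange[2])))
    baseTe <- rlnorm(n, meanlog = 0, sdlog = 0.5)
    mrnaUp <- sample(n, round(config$fracMrnaUp * n))
    teDown <- sample(n, round(config$fracTeDown * n))

    mrnaFold <- teFold <- matrix(1, n, length(config$genotypes),
                                 dimnames = list(genes, config$genotypes))
    for (g in config$genotypes) {
        if (effectApplies(g, config$mrnaEffectGenotype, config$epistasis))
            mrnaFold[mrnaUp, g] <- config$mrnaEffectFold
        if (effectApplies(g, config$teEffectGenotype, config$epistasis))
            teFold[teDown, g] <- config$teEffectFold
    }

    sampleGeno <- rep(config$genotypes, each = config$nBioreps)
    sampleRep <- rep(seq_len(config$nBioreps), times = length(config$genotypes))
    sampleIds <- paste0(sampleGeno, "_r", sampleRep)
    nS <- length(sampleIds)
    libRna <- rlnorm(nS, 0, config$libSizeSd)
    libRpf <- rlnorm(nS, 0, config$libSizeSd)

    drawCounts <- function(mu) {
        if (is.infinite(config$dispersion)) rpois(length(mu), mu)
        else rnbinom(length(mu), mu = mu, size = config$dispersion)
    }
    rna <- rpf <- matrix(0L, n, nS, dimnames = list(genes, sampleIds))
    for (s in seq_len(nS)) {
        g <- sampleGeno[s]
        muRna <- baseMean * mrnaFold[, g] * libRna[s]
        muRpf <- baseMean * mrnaFold[, g] * baseTe * teFold[, g] * libRpf[s]
        rna[, s] <- drawCounts(muRna)
        rpf[, s] <- drawCounts(muRpf)
    }
    storage.mode(rna) <- "integer"
    storage.mode(rpf) <- "integer"

    truth <- data.frame(gene_id = genes, base_rna_mean = baseMean,
                        base_te = baseTe, stringsAsFactors = FALSE)
    for (g in config$genotypes) truth[[paste0("mrna_fold_", g)]] <- mrnaFold[, g]
    for (g in config$genotypes) truth[[paste0("te_fold_", g)]] <- teFold[, g]
    truth$rip_enrichment <- NA_real_
    truth$stai <- NA_real_

    list(experiment = TranslatomeExperiment(rna, rpf, sampleGeno, sampleRep),
         truth = truth)
}

#' Simulate per-gene covariates (RIP-seq enrichment, sTAI)
#'
#' RIP-seq enrichment is drawn with target Pearson correlation
#' \code{config$ripCorrelation} against log2 of the gene's true TE effect in
#' the TE-effect genotype; sTAI codon-optimality scores are Beta-distributed
#' in (0, 1) with mean \code{config$staiMean} (default 0.35, the yeast
#' genome average).
#'
#' @param truth truth table from \code{\link{simulateCounts}}.
#' @param config a \code{\link{simConfig}}.
#' @return the truth table with rip_enrichment and stai filled in.
#' @export
simulateCovariates <- function(truth, config) {
    stopifnot(is.data.frame(truth), nrow(truth) >= 2)
    rho <- config$ripCorrelation
    if (abs(rho) >= 1) stop("ripCorrelation must satisfy |r| < 1")
    set.seed(config$seed + 1L)
    n <- nrow(truth)
    teCol <- paste0("te_fold_", config$teEffectGenotype)
    x <- if (teCol %in% names(truth)) log2(truth[[teCol]]) else rep(0, n)
    if (sd(x) == 0) {
        truth$rip_enrichment <- rnorm(n)
    } else {
        z <- rnorm(n)
        truth$rip_enrichment <- rho * scale(x)[, 1] + sqrt(1 - rho^2) * z
    }
    a <- config$staiMean * config$staiConcentration
    b <- (1 - config$staiMean) * config$staiConcentration
    truth$stai <- rbeta(n, a, b)
    truth
}
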