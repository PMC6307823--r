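# Pipeline orchestration: one entry point running any stage (or all of
# them) from files on disk to result tables, with a reproducibility
# manifest. Logging goes to stderr; results go to files only.

# Default fold/significance selections of the genome-wide stage.
defaultSelections <- function() {
    list(
        list(name = "mrna_up_1.4fold_fdr0.01", metric = "mRNA",
             minFold = 1.4, alpha = 0.01, alphaType = "FDR"),
        list(name = "rpf_up_1.33fold_p0.01", metric = "RPF",
             minFold = 1.33, alpha = 0.01, alphaType = "p"),
        list(name = "te_up_1.33fold_p0.1", metric = "TE",
             minFold = 1.33, alpha = 0.1, alphaType = "p"),
        list(name = "mrna_up_2fold_fdr0.01", metric = "mRNA",
             minFold = 2.0, alpha = 0.01, alphaType = "FDR"))
}

# Contrasts of the strain panel: single mutants vs WT, dcp2d-containing
# double mutants vs the dcp2d single mutant.
panelContrasts <- function(genotypes, metric = "mRNA") {
    muts <- setdiff(genotypes, "WT")
    specs <- lapply(muts, function(m) {
        dels <- deletionsOf(m)
        base <- if ("dcp2d" %in% dels && length(dels) > 1) "dcp2d" else "WT"
        if (identical(m, base)) return(NULL)
        contrastSpec(m, base, metric)
    })
    specs <- Filter(Negate(is.null), specs)
    names(specs) <- vapply(specs, function(s)
        paste0(s$mutant, "_vs_", s$baseline), character(1))
    specs
}

writeManifest <- function(outDir, config, inputs = character()) {
    lines <- c(sprintf("tetherTE version: %s", as.character(packageVersion("tetherTE"))),
               sprintf("R version: %s", R.version.string),
               sprintf("seed: %d", config$seed), "config:",
               vapply(names(config), function(k)
                   sprintf("  %s: %s", k, paste(format(config[[k]]), collapse = ", ")),
                   character(1)))
    inputs <- inputs[file.exists(inputs)]
    if (length(inputs)) {
        sums <- tools::md5sum(inputs)
        lines <- c(lines, "inputs:",
                   sprintf("  %s: md5 %s", basename(names(sums)), sums))
    }
    writeLines(lines, file.path(outDir, "manifest.txt"))
}

logMsg <- function(...) message("[tetherTE] ", sprintf(...))

#' Run a pipeline stage
#'
#' Orchestrates the package's stages over files on disk. Subcommands:
#' \describe{
#'   \item{simulate}{write samples.tsv, decay.tsv, gradient.tsv,
#'     counts_rna.tsv, counts_rpf.tsv, samples_meta.tsv, truth.tsv from a
#'     \code{\link{simConfig}}.}
#'   \item{reporter}{samples.tsv -> reporter_summary.tsv.}
#'   \item{decay}{decay.tsv -> halflife.tsv.}
#'   \item{polysome}{gradient.tsv -> distribution.tsv +
#'     perfraction_tests.tsv (first two conditions compared).}
#'   \item{riboseq}{counts + metadata -> genestats_<contrast>.tsv per panel
#'     contrast and genesets/<name>.txt at the default thresholds.}
#'   \item{genesets}{pairwise hypergeometric overlaps of the gene-set files
#'     -> overlaps.tsv.}
#'   \item{all}{everything above in order, on the simulated inputs.}
#' }
#' Given a fixed config (and its seed), reruns are byte-identical. A
#' manifest (versions, seed, config echo, input checksums) is written next
#' to the results.
#'
#' @param subcommand one of simulate, reporter, decay, polysome, riboseq,
#'   genesets, all.
#' @param config a \code{\link{simConfig}} (or path via
#'   \code{\link{readSimConfig}}).
#' @param inputDir directory holding input TSVs (defaults to outDir, so
#'   `all` chains stages).
#' @param outDir output directory, created if needed.
#' @param minTotal,pseudocount,priorDf genome-wide stage tunables.
#' @param constructEffects reporter simulation effects (named list of
#'   c(protein, mrna)); default models strong tethering repression
#'   (0.4, 0.4) versus an MS2-only control.
#' @return invisibly, a character vector of files written.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "reporter", "decay",
                                       "polysome", "riboseq", "genesets"),
                        config = simConfig(), inputDir = outDir,
                        outDir = "tetherTE_out", minTotal = 10,
                        pseudocount = 0, priorDf = 10,
                        constructEffects = list(
                            "MS2-F" = c(protein = 1, mrna = 1),
                            "Scd6-MS2-F" = c(protein = 0.4, mrna = 0.4))) {
    subcommand <- match.arg(subcommand)
    if (is.character(config) && length(config) == 1 && file.exists(config))
        config <- readSimConfig(config)
    stopifnot(inherits(config, "SimConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    emit <- function(df, name) {
        p <- writeTsv(df, file.path(outDir, name))
        written <<- c(written, p)
        logMsg("wrote %s", p)
        p
    }
    inp <- function(name) {
        p <- file.path(inputDir, name)
        if (!file.exists(p)) stop("input file not found: ", p)
        p
    }

    if (subcommand %in% c("simulate", "all")) {
        logMsg("simulating inputs (seed %d)", config$seed)
        samples <- simulateReporterExperiment(config, constructEffects)
        emit(samples, "samples.tsv")
        decay <- simulateDecaySeries(config$decayK, config, nBioreps = 2L)
        emit(decay, "decay.tsv")
        grad <- rbind(
            simulateGradient(7, 15, spread = 1.5, cv = 0.1, nBioreps = 3,
                             condition = "MS2-F", seed = config$seed),
            simulateGradient(4, 15, spread = 1.5, cv = 0.1, nBioreps = 3,
                             condition = "Scd6-MS2-F", seed = config$seed + 1L))
        emit(grad, "gradient.tsv")
        sim <- simulateCounts(config)
        sim$truth <- simulateCovariates(sim$truth, config)
        rna <- data.frame(gene_id = rownames(sim$experiment),
                          rnaCounts(sim$experiment), check.names = FALSE)
        rpf <- data.frame(gene_id = rownames(sim$experiment),
                          rpfCounts(sim$experiment), check.names = FALSE)
        emit(rna, "counts_rna.tsv")
        emit(rpf, "counts_rpf.tsv")
        cd <- SummarizedExperiment::colData(sim$experiment)
        emit(data.frame(sample_id = rownames(cd), genotype = cd$genotype,
                        bioreplicate = cd$bioreplicate), "samples_meta.tsv")
        emit(sim$truth, "truth.tsv")
    }
    if (subcommand %in% c("reporter", "all")) {
        samples <- readReporterSamples(inp("samples.tsv"))
        constructs <- unique(samples$construct)
        if (length(constructs) < 2) stop("need two constructs in samples.tsv")
        treated <- constructs[constructs != "MS2-F"][1]
        control <- if ("MS2-F" %in% constructs) "MS2-F" else constructs[1]
        emit(analyzeReporter(samples, treated, control), "reporter_summary.tsv")
    }
    if (subcommand %in% c("decay", "all")) {
        decay <- readDecayTable(inp("decay.tsv"))
        emit(fitDecayTable(decay), "halflife.tsv")
    }
    if (subcommand %in% c("polysome", "all")) {
        grad <- readGradientTable(inp("gradient.tsv"))
        dist <- gradientDistributions(grad)
        emit(dist, "distribution.tsv")
        conds <- unique(dist$condition)
        if (length(conds) >= 2) {
            m1 <- profileMatrix(dist, conds[1])
            m2 <- profileMatrix(dist, conds[2])
            emit(perFractionTests(m2, m1), "perfraction_tests.tsv")
        }
    }
    if (subcommand %in% c("riboseq", "all")) {
        x <- readTranslatome(inp("counts_rna.tsv"), inp("counts_rpf.tsv"),
                             inp("samples_meta.tsv"))
        sels <- defaultSelections()
        for (metric in c("mRNA", "RPF", "TE")) {
            specs <- panelContrasts(unique(genotypes(x)), metric)
            for (nm in names(specs)) {
                st <- contrastStats(x, specs[[nm]], minTotal = minTotal,
                                    pseudocount = pseudocount,
                                    priorDf = priorDf)
                if (metric == "mRNA")
                    emit(st, sprintf("genestats_%s.tsv", nm))
                for (sl in sels) {
                    if (sl$metric != metric) next
                    gs <- selectSet(st, metric = sl$metric,
                                    minFold = sl$minFold, alpha = sl$alpha,
                                    alphaType = sl$alphaType,
                                    direction = "up",
                                    name = paste0(nm, "_", sl$name))
                    p <- writeGeneSet(gs, file.path(outDir, "genesets",
                                                    paste0(gs@name, ".txt")))
                    written <- c(written, p)
                }
            }
        }
        logMsg("wrote gene sets under %s", file.path(outDir, "genesets"))
    }
    if (subcommand %in% c("genesets", "all")) {
        dir <- file.path(inputDir, "genesets")
        files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
        if (length(files) >= 2) {
            sets <- lapply(files, readGeneSet)
            uni <- length(unique(unlist(lapply(sets, geneIds))))
            rows <- list()
            for (i in seq_along(sets)) for (j in seq_along(sets)) {
                if (i >= j) next
                a <- sets[[i]]; b <- sets[[j]]
                ov <- length(intersect(geneIds(a), geneIds(b)))
                na <- length(geneIds(a)); nb <- length(geneIds(b))
                if (na == 0 || nb == 0 || na > uni || nb > uni) next
                h <- hypergeometricOverlap(uni, na, nb, ov)
                rows[[length(rows) + 1L]] <- data.frame(
                    set_a = a@name, set_b = b@name, n_universe = uni,
                    n_a = na, n_b = nb, n_overlap = ov, p = h$p)
            }
            if (length(rows)) emit(do.call(rbind, rows), "overlaps.tsv")
        }
    }
    writeManifest(outDir, config,
                  inputs = file.path(inputDir,
                                     c("samples.tsv", "decay.tsv", "gradient.tsv",
                                       "counts_rna.tsv", "counts_rpf.tsv",
                                       "samples_meta.tsv")))
    written <- c(written, file.path(outDir, "manifest.txt"))
    invisible(written)
}
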