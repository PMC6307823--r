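#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats coef lm median p.adjust pnorm phyper pt qnorm quantile
#'   rbeta rlnorm rnbinom rnorm rpois runif sd setNames t.test cor.test var
#' @importFrom utils read.delim write.table packageVersion
NULL

#' TranslatomeExperiment: paired RPF and RNA count matrices
#'
#' An S4 container for a ribosome-profiling experiment: two assays named
#' \code{"rna"} (RNA-Seq counts per CDS) and \code{"rpf"} (ribosome-protected
#' fragment counts per CDS), over the same genes and samples, with sample
#' annotations \code{genotype} and \code{bioreplicate} in \code{colData}.
#' Extends \linkS4class{SummarizedExperiment}; all SummarizedExperiment
#' accessors apply.
#'
#' @slot .
#'   inherited from \linkS4class{SummarizedExperiment}.
#' @aliases TranslatomeExperiment-class
#' @exportClass TranslatomeExperiment
setClass("TranslatomeExperiment", contains = "SummarizedExperiment")

setValidity("TranslatomeExperiment", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("rna", "rpf") %in% an))
        msg <- c(msg, "assays must include 'rna' and 'rpf'")
    else {
        for (a in c("rna", "rpf")) {
            m <- SummarizedExperiment::assay(object, a)
            if (any(m < 0)) msg <- c(msg, sprintf("assay '%s' has negative counts", a))
            if (any(abs(m - round(m)) > 1e-8))
                msg <- c(msg, sprintf("assay '%s' has non-integral counts", a))
        }
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("genotype", "bioreplicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'genotype' and 'bioreplicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
})

#' Construct a TranslatomeExperiment
#'
#' @param rna,rpf integer gene-by-sample count matrices with identical
#'   dimnames (gene ids as rownames, sample ids as colnames).
#' @param genotype character vector of genotype labels, one per sample.
#' @param bioreplicate identifiers distinguishing biological replicates
#'   within a genotype.
#' @return A \linkS4class{TranslatomeExperiment}.
#' @examples
#' rna <- matrix(rpois(8, 50), 2, dimnames = list(c("g1","g2"), paste0("s", 1:4)))
#' rpf <- matrix(rpois(8, 30), 2, dimnames = dimnames(rna))
#' te <- TranslatomeExperiment(rna, rpf,
#'                             genotype = rep(c("WT", "scd6d"), each = 2),
#'                             bioreplicate = rep(1:2, 2))
#' @export
TranslatomeExperiment <- function(rna, rpf, genotype, bioreplicate) {
    stopifnot(identical(dim(rna), dim(rpf)),
              identical(dimnames(rna), dimnames(rpf)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(rna = rna, rpf = rpf),
        colData = S4Vectors::DataFrame(genotype = as.character(genotype),
                                       bioreplicate = as.character(bioreplicate),
                                       row.names = colnames(rna)))
    new("TranslatomeExperiment", se)
}

#' @rdname TranslatomeExperiment
#' @param x a TranslatomeExperiment.
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))

#' @rdname TranslatomeExperiment
#' @export
setGeneric("rpfCounts", function(x) standardGeneric("rpfCounts"))

#' @rdname TranslatomeExperiment
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname TranslatomeExperiment
#' @export
setMethod("rnaCounts", "TranslatomeExperiment", function(x)
    SummarizedExperiment::assay(x, "rna"))

#' @rdname TranslatomeExperiment
#' @export
setMethod("rpfCounts", "TranslatomeExperiment", function(x)
    SummarizedExperiment::assay(x, "rpf"))

#' @rdname TranslatomeExperiment
#' @export
setMethod("genotypes", "TranslatomeExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$genotype))

setMethod("show", "TranslatomeExperiment", function(object) {
    callNextMethod()
    cat("genotypes:", paste(unique(genotypes(object)), collapse = ", "), "\n")
})

#' RatioWithError: a ratio of two summarized means with propagated SEM
#'
#' Holds the ratio X/Y of two replicate means together with its propagated
#' standard error (X/Y) * sqrt((SE_x/X)^2 + (SE_y/Y)^2), the standard
#' first-order (delta-method) propagation for a ratio expressed through
#' relative SEMs.
#'
#' @slot ratio the ratio of means X/Y.
#' @slot sem the propagated standard error of the ratio.
#' @slot nNum,nDen replicate counts behind numerator and denominator.
#' @aliases RatioWithError-class
#' @exportClass RatioWithError
setClass("RatioWithError",
         representation(ratio = "numeric", sem = "numeric",
                        nNum = "integer", nDen = "integer"))

setValidity("RatioWithError", function(object) {
    if (length(object@ratio) != 1L || length(object@sem) != 1L)
        return("ratio and sem must be scalars")
    if (!is.na(object@sem) && object@sem < 0) return("sem must be >= 0")
    TRUE
})

setMethod("show", "RatioWithError", function(object) {
    cat(sprintf("ratio %.4g +/- %.3g (propagated SEM; n = %d/%d)\n",
                object@ratio, object@sem, object@nNum, object@nDen))
})

#' @rdname RatioWithError-class
#' @param x a RatioWithError.
#' @export
setGeneric("ratioValue", function(x) standardGeneric("ratioValue"))

#' @rdname RatioWithError-class
#' @export
setGeneric("propagatedSem", function(x) standardGeneric("propagatedSem"))

#' @rdname RatioWithError-class
#' @export
setMethod("ratioValue", "RatioWithError", function(x) x@ratio)

#' @rdname RatioWithError-class
#' @export
setMethod("propagatedSem", "RatioWithError", function(x) x@sem)

#' HalfLife: fitted first-order decay parameters
#'
#' Result of an ordinary least-squares fit of log percent-remaining against
#' time over a chosen window. The half-life is computed as constant/k with
#' constant 0.693 by default (the rounded ln 2 conventionally printed for
#' shutoff time courses; set \code{halfLifeConstant = log(2)} for the exact
#' value).
#'
#' @slot k first-order decay rate, per minute (-slope of the log-linear fit).
#' @slot tHalf half-life in minutes, \code{halfLifeConstant / k}.
#' @slot halfLifeConstant the numerator used for tHalf.
#' @slot window the (first, last) time bounds of the fit window.
#' @slot rSquared goodness of fit of the log-linear regression.
#' @slot nPoints number of time points used.
#' @slot valid FALSE when k <= 0 (no decay detectable).
#' @aliases HalfLife-class
#' @exportClass HalfLife
setClass("HalfLife",
         representation(k = "numeric", tHalf = "numeric",
                        halfLifeConstant = "numeric", window = "numeric",
                        rSquared = "numeric", nPoints = "integer",
                        valid = "logical"))

setValidity("HalfLife", function(object) {
    if (length(object@window) != 2L) return("window must be length 2")
    if (isTRUE(object@valid) &&
        abs(object@tHalf * object@k - object@halfLifeConstant) > 1e-9)
        return("tHalf * k must equal halfLifeConstant")
    TRUE
})

setMethod("show", "HalfLife", function(object) {
    cat(sprintf("half-life %.3g min (k = %.4g /min, r^2 = %.3f, %d points in [%g, %g])%s\n",
                object@tHalf, object@k, object@rSquared, object@nPoints,
                object@window[1], object@window[2],
                if (object@valid) "" else " [INVALID: k <= 0]"))
})

#' @rdname HalfLife-class
#' @param x a HalfLife.
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @rdname HalfLife-class
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname HalfLife-class
#' @export
setMethod("decayRate", "HalfLife", function(x) x@k)

#' @rdname HalfLife-class
#' @export
setMethod("halfLife", "HalfLife", function(x) x@tHalf)

#' GeneSet: a threshold-selected set of genes with selection provenance
#'
#' @slot name set label.
#' @slot geneIds character vector of member gene ids.
#' @slot selection list recording the selection rule
#'   (metric, minFold, alpha, alphaType, direction).
#' @aliases GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet",
         representation(name = "character", geneIds = "character",
                        selection = "list"))

setValidity("GeneSet", function(object) {
    if (anyDuplicated(object@geneIds)) return("duplicate gene ids in set")
    TRUE
})

setMethod("show", "GeneSet", function(object) {
    sel <- object@selection
    cat(sprintf("GeneSet '%s': %d genes", object@name, length(object@geneIds)))
    if (length(sel))
        cat(sprintf(" [%s >= %.3g-fold %s, %s %s %.3g]", sel$metric, sel$minFold,
                    sel$direction, sel$alphaType,
                    if (identical(sel$alphaType, "FDR")) "<" else "<=", sel$alpha))
    cat("\n")
})

#' @rdname GeneSet-class
#' @param x a GeneSet.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(x) x@geneIds)

#' @rdname GeneSet-class
#' @export
setGeneric("selectionRule", function(x) standardGeneric("selectionRule"))

#' @rdname GeneSet-class
#' @export
setMethod("selectionRule", "GeneSet", function(x) x@selection)
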