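# Strict TSV input/output. Every table is tab-delimited UTF-8 with a single
# header line, no quoting, '.' decimal; readers fail with the file name and
# the missing columns rather than guessing.

readTsvStrict <- function(path, requiredCols = character()) {
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- read.delim(path, sep = "\t", quote = "", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    missing <- setdiff(requiredCols, names(df))
    if (length(missing))
        stop(sprintf("%s: missing required column(s): %s", path,
                     paste(missing, collapse = ", ")))
    df
}

#' Write a table as strict TSV
#'
#' @param df data.frame.
#' @param path output path (directories created as needed).
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a reporter sample table
#'
#' Expects columns strain, construct, bioreplicate, protein_signal,
#' loading_signal and ct_reporter_1..k / ct_reference_1..k.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readReporterSamples <- function(path) {
    df <- readTsvStrict(path, c("strain", "construct", "bioreplicate",
                                "protein_signal", "loading_signal"))
    if (!any(grepl("^ct_reporter_", names(df))) ||
        !any(grepl("^ct_reference_", names(df))))
        stop(path, ": missing ct_reporter_*/ct_reference_* columns")
    df
}

#' Read a decay time-course table
#'
#' @param path TSV with columns bioreplicate, time_min, relative_abundance.
#' @return data.frame.
#' @export
readDecayTable <- function(path)
    readTsvStrict(path, c("bioreplicate", "time_min", "relative_abundance"))

#' Read a polysome gradient table
#'
#' @param path TSV with columns condition, bioreplicate, fraction and either
#'   signal or ct_1..k.
#' @return data.frame.
#' @export
readGradientTable <- function(path) {
    df <- readTsvStrict(path, c("condition", "bioreplicate", "fraction"))
    if (!"signal" %in% names(df) && !any(grepl("^ct_[0-9]+$", names(df))))
        stop(path, ": needs a 'signal' column or ct_1..k columns")
    df
}

#' Read a gene-by-sample count matrix
#'
#' First column gene_id, remaining columns one sample each, integer cells.
#'
#' @param path TSV path.
#' @return integer matrix with gene rownames.
#' @export
readCountMatrix <- function(path) {
    df <- readTsvStrict(path, "gene_id")
    m <- as.matrix(df[setdiff(names(df), "gene_id")])
    if (!is.numeric(m)) stop(path, ": non-numeric count cells")
    rownames(m) <- df$gene_id
    storage.mode(m) <- "integer"
    m
}

#' Read count matrices and sample metadata into a TranslatomeExperiment
#'
#' @param rnaPath,rpfPath count matrix TSVs (same genes, same samples).
#' @param metaPath TSV with columns sample_id, genotype, bioreplicate.
#' @return a \linkS4class{TranslatomeExperiment}.
#' @export
readTranslatome <- function(rnaPath, rpfPath, metaPath) {
    rna <- readCountMatrix(rnaPath)
    rpf <- readCountMatrix(rpfPath)
    meta <- readTsvStrict(metaPath, c("sample_id", "genotype", "bioreplicate"))
    if (!identical(rownames(rna), rownames(rpf)))
        stop("gene ids differ between RNA and RPF matrices")
    if (!setequal(colnames(rna), meta$sample_id))
        stop("sample ids differ between count matrices and metadata")
    i <- match(colnames(rna), meta$sample_id)
    rpf <- rpf[, colnames(rna), drop = FALSE]
    TranslatomeExperiment(rna, rpf, genotype = meta$genotype[i],
                          bioreplicate = meta$bioreplicate[i])
}

#' Read a simulation config from a YAML key-value file
#'
#' Keys mirror the arguments of \code{\link{simConfig}}; unknown keys are an
#' error so typos surface.
#'
#' @param path YAML file.
#' @return a validated \code{\link{simConfig}}.
#' @export
readSimConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    known <- names(formals(simConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop(path, ": unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(simConfig, vals)
}

#' Write a gene set as one id per line
#'
#' @param set a \linkS4class{GeneSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneSet <- function(set, path) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    writeLines(geneIds(set), path)
    invisible(path)
}

#' Read a gene set file (one id per line)
#'
#' @param path input path.
#' @param name set label (defaults to the file name).
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path)) stop("gene set file not found: ", path)
    ids <- readLines(path)
    ids <- ids[nzchar(ids)]
    new("GeneSet", name = name, geneIds = ids, selection = list())
}
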