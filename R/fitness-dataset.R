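#' Construct a FitnessDataset
#'
#' Bundles the fitness-defect and P-value matrices of a pooled
#' deletion-strain screen with its condition table. Matrices are genes
#' by conditions; missing measurements stay \code{NA}.
#'
#' @param fd numeric matrix of log2-ratio fitness-defect scores (higher
#'   means more sensitive), genes in rows, conditions in columns.
#' @param pval numeric matrix of one-sided sensitivity P-values with the
#'   same dimensions and dimnames as \code{fd}.
#' @param conditions data.frame with one row per condition and columns
#'   \code{condition_id}, \code{compound_id} and optionally
#'   \code{concentration}, \code{timepoint}.
#' @param zygosity \code{"heterozygous"} or \code{"homozygous"}.
#' @return a validated \linkS4class{FitnessDataset}.
#' @examples
#' fd <- matrix(rnorm(6), 3, 2,
#'              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' pv <- matrix(runif(6), 3, 2, dimnames = dimnames(fd))
#' cond <- data.frame(condition_id = c("c1", "c2"),
#'                    compound_id = c("drugA", "drugA"))
#' ds <- FitnessDataset(fd, pv, cond, "heterozygous")
#' @export
FitnessDataset <- function(fd, pval, conditions, zygosity) {
    fd <- as.matrix(fd)
    pval <- as.matrix(pval)
    if (!identical(dim(fd), dim(pval)))
        stop("fd and pval matrices must have identical dimensions")
    conditions <- as.data.frame(conditions)
    if (!all(c("condition_id", "compound_id") %in% colnames(conditions)))
        stop("conditions needs 'condition_id' and 'compound_id' columns")
    if (nrow(conditions) != ncol(fd))
        stop("condition table must have one row per matrix column")
    if (is.null(colnames(fd)))
        colnames(fd) <- colnames(pval) <- conditions$condition_id
    if (!identical(colnames(fd), as.character(conditions$condition_id)))
        stop("matrix column names must match the condition table")
    if (!"concentration" %in% colnames(conditions))
        conditions$concentration <- NA_character_
    if (!"timepoint" %in% colnames(conditions))
        conditions$timepoint <- NA_character_
    cd <- DataFrame(conditions, row.names = conditions$condition_id)
    se <- SummarizedExperiment(assays = list(fd = fd, pval = pval),
                               colData = cd)
    new("FitnessDataset", se, zygosity = zygosity)
}

#' @rdname FitnessDataset-class
#' @export
setMethod("fdScores", "FitnessDataset", function(x) assay(x, "fd"))

#' @rdname FitnessDataset-class
#' @export
setMethod("pValues", "FitnessDataset", function(x) assay(x, "pval"))

#' @rdname FitnessDataset-class
#' @export
setMethod("zygosity", "FitnessDataset", function(x) x@zygosity)

#' @rdname FitnessDataset-class
#' @export
setMethod("geneIds", "FitnessDataset", function(x) rownames(x))

#' @rdname FitnessDataset-class
#' @export
setMethod("conditionIds", "FitnessDataset", function(x) colnames(x))

#' @rdname FitnessDataset-class
#' @export
setMethod("compoundIds", "FitnessDataset",
    function(x) as.character(colData(x)$compound_id))

setMethod("show", "FitnessDataset", function(object) {
    cat(sprintf("FitnessDataset (%s): %d genes x %d conditions (%d compounds)\n",
        object@zygosity, nrow(object), ncol(object),
        length(unique(colData(object)$compound_id))))
    cat(sprintf("  missing fd entries: %d\n", sum(is.na(assay(object, "fd")))))
})

## ---- file I/O -------------------------------------------------------------

.readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                            na.strings = c("NA", ""))
    m <- as.matrix(df)
    if (!is.numeric(m))
        stop("non-numeric cells in ", path,
             " (only 'NA' or empty cells may be missing)")
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
    if (anyDuplicated(colnames(m))) stop("duplicate condition ids in ", path)
    m
}

#' Read a fitness dataset from TSV files
#'
#' Reads the fitness-defect matrix at \code{<path>.tsv} (genes in rows,
#' conditions in columns, \code{NA} or empty for missing), the parallel
#' P-value matrix at \code{<path>.pval.tsv} and the condition table at
#' \code{<path>.conditions.tsv} (columns condition_id, compound_id,
#' concentration, timepoint).
#'
#' @param path file path prefix (without the .tsv extension).
#' @param zygosity \code{"heterozygous"} or \code{"homozygous"}.
#' @return a validated \linkS4class{FitnessDataset}.
#' @seealso [writeFitnessDataset()]
#' @export
loadFitnessDataset <- function(path, zygosity) {
    fd <- .readMatrixTsv(paste0(path, ".tsv"))
    pval <- .readMatrixTsv(paste0(path, ".pval.tsv"))
    if (!identical(dim(fd), dim(pval)) ||
        !identical(dimnames(fd), dimnames(pval)))
        stop("fd and pval files disagree in dimensions or ids")
    conditions <- utils::read.delim(paste0(path, ".conditions.tsv"),
                                    check.names = FALSE,
                                    colClasses = "character")
    FitnessDataset(fd, pval, conditions, zygosity)
}

#' Write a fitness dataset to TSV files
#'
#' Inverse of [loadFitnessDataset()]: writes \code{<path>.tsv},
#' \code{<path>.pval.tsv} and \code{<path>.conditions.tsv}. Round-trips
#' are lossless for values, ordering and missingness.
#'
#' @param ds a \linkS4class{FitnessDataset}.
#' @param path file path prefix.
#' @return invisibly, the three file paths written.
#' @export
writeFitnessDataset <- function(ds, path) {
    writeMat <- function(m, file) {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    files <- paste0(path, c(".tsv", ".pval.tsv", ".conditions.tsv"))
    writeMat(fdScores(ds), files[1])
    writeMat(pValues(ds), files[2])
    utils::write.table(as.data.frame(colData(ds)), files[3], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(files)
}
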