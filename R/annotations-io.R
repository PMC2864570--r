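#' Construct a FingerprintMatrix
#'
#' @param bits 0/1 matrix, compounds in rows (rownames required), motifs
#'   in columns. Column names default to \code{m327 ... m(326+F)},
#'   mirroring the PubChem substructure key numbering.
#' @param form representation tag; new matrices are \code{"binary"}.
#' @param docCounts per-motif compound counts; computed from
#'   \code{bits} when the form is binary.
#' @return a \linkS4class{FingerprintMatrix}.
#' @export
FingerprintMatrix <- function(bits, form = "binary", docCounts = NULL) {
    bits <- as.matrix(bits)
    storage.mode(bits) <- "double"
    if (is.null(colnames(bits)))
        colnames(bits) <- paste0("m", seq_len(ncol(bits)) + 326L)
    if (is.null(docCounts)) {
        if (form != "binary")
            stop("docCounts must be supplied for non-binary forms")
        docCounts <- as.integer(colSums(bits != 0))
    }
    new("FingerprintMatrix", bits = bits, form = form,
        docCounts = as.integer(docCounts))
}

#' @rdname FingerprintMatrix
#' @param x a \linkS4class{FingerprintMatrix}
#' @export
setMethod("scores", "FingerprintMatrix", function(x) x@bits)

#' @rdname FingerprintMatrix
#' @export
fingerprintForm <- function(x) x@form

#' @rdname FingerprintMatrix
#' @export
motifCounts <- function(x) {
    stats::setNames(x@docCounts, colnames(x@bits))
}

setMethod("show", "FingerprintMatrix", function(object) {
    cat(sprintf("FingerprintMatrix (%s): %d compounds x %d motifs\n",
        object@form, nrow(object@bits), ncol(object@bits)))
})

## ---- gene annotations -----------------------------------------------------

#' Read and validate gene annotations
#'
#' Tab-separated table with columns \code{gene_id}, \code{essential}
#' (0/1), \code{hom_rich_medium_fd} (rich-medium homozygous fitness
#' phenotype; NA for essential genes without a homozygous strain),
#' \code{paralog_partner} (empty when none) and \code{processes}
#' (semicolon-separated biological-process labels, at most 32 distinct
#' labels dataset-wide).
#'
#' @param path TSV file path.
#' @return data.frame with one row per gene.
#' @export
readGeneAnnotations <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("NA", ""))
    df$gene_id <- as.character(df$gene_id)
    df$essential <- as.logical(df$essential)
    df$paralog_partner <- as.character(df$paralog_partner)
    df$processes <- as.character(df$processes)
    validateGeneAnnotations(df)
    df
}

#' @rdname readGeneAnnotations
#' @param ann gene-annotation data.frame.
#' @export
writeGeneAnnotations <- function(ann, path) {
    out <- ann
    out$essential <- as.integer(out$essential)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readGeneAnnotations
#' @export
validateGeneAnnotations <- function(ann) {
    req <- c("gene_id", "essential", "hom_rich_medium_fd",
             "paralog_partner", "processes")
    if (!all(req %in% colnames(ann)))
        stop("gene annotations need columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids")
    partner <- stats::setNames(ann$paralog_partner, ann$gene_id)
    has <- !is.na(partner)
    if (any(has)) {
        if (!all(partner[has] %in% ann$gene_id))
            stop("paralog partners must be known genes")
        back <- partner[partner[has]]
        if (!identical(unname(back), names(partner[has])))
            stop("paralog relation must be symmetric")
    }
    labels <- unique(unlist(strsplit(ann$processes[!is.na(ann$processes)],
                                     ";", fixed = TRUE)))
    if (length(labels) > 32L)
        stop("more than 32 distinct process labels")
    invisible(TRUE)
}

#' Split semicolon-separated process labels into a named list
#'
#' @param ann gene-annotation data.frame.
#' @return named list, gene id to character vector of process labels.
#' @export
geneProcesses <- function(ann) {
    out <- strsplit(ifelse(is.na(ann$processes), "", ann$processes),
                    ";", fixed = TRUE)
    stats::setNames(out, ann$gene_id)
}

## ---- gene sets (GMT) ------------------------------------------------------

#' Read or write gene sets in GMT format
#'
#' GMT lines are \code{set_id<TAB>description<TAB>member...}. Used for
#' protein-complex catalogs and process gene sets.
#'
#' @param path GMT file path.
#' @return named list of member character vectors, with a
#'   \code{description} attribute per element preserved on write.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(ids)) stop("duplicate set ids in ", path)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- ids
    attr(sets, "descriptions") <- stats::setNames(
        vapply(parts, `[`, "", 2L), ids)
    sets
}

#' @rdname readGmt
#' @param sets named list of member vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    lines <- vapply(names(sets), function(id)
        paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Restrict a complex catalog for essentiality analysis
#'
#' Keeps complexes with at least \code{minMembers} members among the
#' supplied gene universe (by default any gene).
#'
#' @param catalog named list of member gene vectors.
#' @param genes optional character vector restricting the members.
#' @param minMembers minimum member count (2 for essentiality work).
#' @return filtered named list.
#' @export
filterComplexCatalog <- function(catalog, genes = NULL, minMembers = 2L) {
    if (!is.null(genes))
        catalog <- lapply(catalog, intersect, y = genes)
    catalog[vapply(catalog, length, 0L) >= minMembers]
}

## ---- reference network and interaction sets -------------------------------

#' Canonicalize an edge list of unordered gene pairs
#'
#' Orders each pair lexicographically, drops self-pairs and duplicate
#' unordered pairs.
#'
#' @param pairs data.frame or 2-column matrix of gene ids.
#' @return data.frame with columns gene1 <= gene2, unique rows.
#' @export
canonicalPairs <- function(pairs) {
    a <- as.character(pairs[[1]])
    b <- as.character(pairs[[2]])
    keep <- a != b
    g1 <- pmin(a[keep], b[keep])
    g2 <- pmax(a[keep], b[keep])
    out <- unique(data.frame(gene1 = g1, gene2 = g2,
                             stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

#' @rdname canonicalPairs
#' @param path two-column TSV edge list with a header row.
#' @export
readEdgeList <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    canonicalPairs(df)
}

#' @rdname canonicalPairs
#' @param edges canonical pair data.frame.
#' @export
writeEdgeList <- function(edges, path) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Validate a drug-protein interaction set
#'
#' Interaction sets are data.frames with columns \code{compound_id},
#' \code{gene_id}, \code{label} (\code{"positive"}/\code{"negative"})
#' and \code{source}. No (compound, gene) pair may carry conflicting
#' labels.
#'
#' @param interactions interaction data.frame.
#' @return invisibly TRUE, or an error.
#' @export
validateInteractions <- function(interactions) {
    req <- c("compound_id", "gene_id", "label")
    if (!all(req %in% colnames(interactions)))
        stop("interaction set needs columns: ", paste(req, collapse = ", "))
    if (!all(interactions$label %in% c("positive", "negative")))
        stop("labels must be 'positive' or 'negative'")
    key <- paste(interactions$compound_id, interactions$gene_id, sep = "\r")
    nlab <- tapply(interactions$label, key, function(l) length(unique(l)))
    if (any(nlab > 1L))
        stop("conflicting labels for the same (compound, gene) pair")
    invisible(TRUE)
}

#' @rdname validateInteractions
#' @param path three/four-column TSV with a header row.
#' @export
readInteractions <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (!"source" %in% colnames(df)) df$source <- NA_character_
    validateInteractions(df)
    df
}

#' @rdname validateInteractions
#' @export
writeInteractions <- function(interactions, path) {
    utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- compound annotations -------------------------------------------------

#' Read compound annotations and fingerprints
#'
#' The compound table is TSV with columns \code{compound_id},
#' \code{smiles} (may be empty), \code{atc_codes}
#' (semicolon-separated 7-character WHO ATC codes, may be empty) and
#' optional \code{tested_het}/\code{tested_hom} flags. The fingerprint
#' matrix is a compounds-by-motifs TSV of 0/1 bits.
#'
#' @param path TSV file path.
#' @return data.frame (compound table) or
#'   \linkS4class{FingerprintMatrix}.
#' @export
readCompoundAnnotations <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("NA", ""),
                            colClasses = "character")
    if (anyDuplicated(df$compound_id)) stop("duplicate compound ids")
    for (col in c("tested_het", "tested_hom"))
        if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
    codes <- unlist(atcCodes(df))
    if (length(codes)) .checkAtc(codes)
    df
}

#' @rdname readCompoundAnnotations
#' @param compounds compound annotation data.frame.
#' @export
writeCompoundAnnotations <- function(compounds, path) {
    utils::write.table(compounds, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readCompoundAnnotations
#' @export
readFingerprintMatrix <- function(path) {
    FingerprintMatrix(.readMatrixTsv(path))
}

#' @rdname readCompoundAnnotations
#' @param fp a \linkS4class{FingerprintMatrix}.
#' @export
writeFingerprintMatrix <- function(fp, path) {
    df <- data.frame(compound_id = rownames(scores(fp)), scores(fp),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Split a compound table's ATC annotation into a named list
#'
#' @param compounds compound annotation data.frame.
#' @return named list, compound id to character vector of ATC codes.
#' @export
atcCodes <- function(compounds) {
    raw <- compounds$atc_codes
    out <- strsplit(ifelse(is.na(raw), "", raw), ";", fixed = TRUE)
    stats::setNames(out, compounds$compound_id)
}

.checkAtc <- function(codes) {
    bad <- !grepl("^[A-Z0-9]{7}$", codes)
    if (any(bad))
        stop("malformed ATC code(s): ",
             paste(unique(codes[bad]), collapse = ", "),
             " (expected 7 uppercase alphanumeric characters)")
    invisible(TRUE)
}
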