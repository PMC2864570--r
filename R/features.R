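#' Names of the 20 learning features
#'
#' ratio and pvalue (collapsed heterozygous fitness defect and its
#' P-value), genefreq and drugfreq (sensitivity frequencies), hompheno
#' (rich-medium homozygous phenotype), struct_enrichment, struct_count
#' and struct_similarity (shared-substructure features over the
#' compounds sensitizing the gene), ten secondary_ligands slots (the
#' gene's fitness defects in the query compound's top ten co-inhibiting
#' compounds) and their secondary_mean and secondary_median summaries.
#'
#' @return character vector of length 20.
#' @export
featureNames <- function() {
    c("ratio", "pvalue", "genefreq", "drugfreq", "hompheno",
      "struct_enrichment", "struct_count", "struct_similarity",
      paste0("secondary_ligands_", 1:10),
      "secondary_mean", "secondary_median")
}

.sensitiveCompounds <- function(gene, calls) {
    colnames(calls)[calls[gene, ]]
}

#' Risk-ratio substructure enrichment of a gene's sensitizing compounds
#'
#' Over the set C_i of compounds inducing significant sensitivity in
#' gene g_i, scores every candidate motif m by the log risk ratio
#' RR = ln(P(m | C_i) / P(m)), where P(m | C_i) is the motif's
#' frequency within C_i and P(m) its frequency across all compounds.
#' Motif pairs (both motifs present in a compound) are scored the same
#' way, allowing for binding on non-contiguous structural areas. The
#' maximum RR over single motifs and pairs is returned. Candidates are
#' restricted to motifs (or pairs) present in at least one member of
#' C_i; with \code{pairSpecific = TRUE} (default) they are further
#' restricted to the query compound's own motif set M_c, making the
#' feature specific to the (gene, compound) pair.
#'
#' @param gene gene id.
#' @param calls compound-level significant-call matrix.
#' @param fp a binary \linkS4class{FingerprintMatrix}.
#' @param queryCompound the compound of the pair under consideration.
#' @param pairSpecific restrict candidates to the query compound's
#'   motifs.
#' @return list with \code{rr}, \code{motifs} (one or two motif names),
#'   \code{pInSet}, \code{pGlobal}, \code{nSet} and \code{flag}
#'   (TRUE when C_i was empty and the 0 sentinel was returned).
#' @export
structEnrichment <- function(gene, calls, fp, queryCompound,
                             pairSpecific = TRUE) {
    bits <- scores(fp)
    ci <- .sensitiveCompounds(gene, calls)
    ci <- intersect(ci, rownames(bits))
    if (!length(ci))
        return(list(rr = 0, motifs = character(), pInSet = NA_real_,
                    pGlobal = NA_real_, nSet = 0L, flag = TRUE))
    cand <- if (pairSpecific) {
        if (!queryCompound %in% rownames(bits))
            stop("unknown query compound: ", queryCompound)
        colnames(bits)[bits[queryCompound, ] == 1]
    } else colnames(bits)
    inSet <- colMeans(bits[ci, cand, drop = FALSE])
    cand <- cand[inSet > 0]            # present in >= 1 member of C_i
    if (!length(cand))
        return(list(rr = 0, motifs = character(), pInSet = NA_real_,
                    pGlobal = NA_real_, nSet = length(ci), flag = TRUE))
    pSet <- colMeans(bits[ci, cand, drop = FALSE])
    pAll <- colMeans(bits[, cand, drop = FALSE])
    rr <- log(pSet / pAll)
    bestSingle <- which.max(rr)
    best <- list(rr = rr[[bestSingle]], motifs = cand[bestSingle],
                 pInSet = pSet[[bestSingle]], pGlobal = pAll[[bestSingle]])
    if (length(cand) >= 2L) {
        sub <- bits[, cand, drop = FALSE]
        subCi <- sub[ci, , drop = FALSE]
        pairs <- utils::combn(length(cand), 2L)
        pairSet <- colMeans(subCi[, pairs[1, ], drop = FALSE] *
                            subCi[, pairs[2, ], drop = FALSE])
        keep <- pairSet > 0
        if (any(keep)) {
            pairAll <- colMeans(sub[, pairs[1, keep], drop = FALSE] *
                                sub[, pairs[2, keep], drop = FALSE])
            pairRr <- log(pairSet[keep] / pairAll)
            bp <- which.max(pairRr)
            if (pairRr[bp] > best$rr) {
                sel <- which(keep)[bp]
                best <- list(rr = pairRr[[bp]],
                             motifs = cand[pairs[, sel]],
                             pInSet = pairSet[keep][[bp]],
                             pGlobal = pairAll[[bp]])
            }
        }
    }
    c(best, list(nSet = length(ci), flag = FALSE))
}

#' Count sensitizing compounds sharing a motif with the query
#'
#' k is the largest number of other compounds in C_i (the compounds
#' sensitizing the gene) that all share one common motif with the
#' query compound: for each motif of the query, count the other
#' members of C_i carrying it, and take the maximum over motifs. Zero
#' when no other member of C_i shares any motif with the query.
#'
#' @inheritParams structEnrichment
#' @param compound the query compound id.
#' @return integer k.
#' @export
structCount <- function(gene, compound, calls, fp) {
    bits <- scores(fp)
    if (!compound %in% rownames(bits))
        stop("unknown compound: ", compound)
    ci <- setdiff(intersect(.sensitiveCompounds(gene, calls),
                            rownames(bits)), compound)
    motifs <- colnames(bits)[bits[compound, ] == 1]
    if (!length(ci) || !length(motifs)) return(0L)
    max(as.integer(colSums(bits[ci, motifs, drop = FALSE] == 1)))
}

#' Mean pairwise structural similarity of a gene's sensitizing
#' compounds
#'
#' The average Tanimoto similarity over all unordered pairs within C_i,
#' computed from the supplied fingerprint representation (the raw
#' 554-key binary fingerprints by default in [buildFeatureTable()]).
#' Returns 0 with a flag when C_i has fewer than two members.
#'
#' @inheritParams structEnrichment
#' @return list with \code{value} and \code{flag}.
#' @export
structSimilarityMean <- function(gene, calls, fp) {
    bits <- scores(fp)
    ci <- intersect(.sensitiveCompounds(gene, calls), rownames(bits))
    if (length(ci) < 2L) return(list(value = 0, flag = TRUE))
    Tm <- tanimotoMatrix(
        new("FingerprintMatrix", bits = bits[ci, , drop = FALSE],
            form = fingerprintForm(fp),
            docCounts = as.integer(colSums(bits[ci, , drop = FALSE] != 0))))
    list(value = mean(Tm[upper.tri(Tm)]), flag = FALSE)
}

#' Secondary-ligand fitness-defect features
#'
#' Ranks the other compounds by their co-inhibition with the query
#' compound (descending, ties broken by compound id) and takes the
#' gene's fitness defects in the top ten 'secondary compounds' as ten
#' feature slots, plus their mean and median. Missing fitness defects
#' and unfilled slots (fewer than ten co-inhibiting compounds
#' available) are 0; the mean and median are taken over the ten slot
#' values.
#'
#' @param compound query compound id.
#' @param gene gene id.
#' @param cm heterozygous \linkS4class{CoinhibitionMatrix}.
#' @param ds replicate-collapsed heterozygous
#'   \linkS4class{FitnessDataset}.
#' @return named numeric vector of length 12 (secondary_ligands_1..10,
#'   secondary_mean, secondary_median).
#' @export
secondaryLigandFeatures <- function(compound, gene, cm, ds) {
    S <- scores(cm)
    if (!compound %in% rownames(S))
        stop("compound absent from co-inhibition matrix: ", compound)
    cors <- S[compound, setdiff(colnames(S), compound)]
    cors <- cors[!is.na(cors)]
    ranked <- names(cors)[order(-cors, names(cors))]
    top <- utils::head(ranked, 10L)
    slots <- numeric(10L)
    fd <- fdScores(ds)
    if (gene %in% rownames(fd)) {
        for (i in seq_along(top)) {
            v <- if (top[i] %in% colnames(fd)) fd[gene, top[i]] else NA_real_
            slots[i] <- if (is.na(v)) 0 else v
        }
    }
    out <- c(slots, mean(slots), stats::median(slots))
    names(out) <- c(paste0("secondary_ligands_", 1:10),
                    "secondary_mean", "secondary_median")
    out
}

#' Assemble the 20-feature learning table
#'
#' One row per (gene, compound) pair with exactly the 20 named
#' features. \code{ratio} and \code{pvalue} come from the
#' replicate-collapsed heterozygous data (missing fd falls back to 0
#' and missing P to 1, flagged in the metadata); frequencies come from
#' the significant-call matrix; \code{hompheno} is the gene's
#' rich-medium homozygous phenotype (0 when unmeasured, e.g. essential
#' genes); the structure and secondary-ligand features are documented
#' in their own functions.
#'
#' @param pairs data.frame with columns gene_id, compound_id and
#'   optionally label.
#' @param ds replicate-collapsed heterozygous
#'   \linkS4class{FitnessDataset}.
#' @param annotations gene-annotation data.frame.
#' @param calls compound-level significant-call matrix for \code{ds}.
#' @param fp binary \linkS4class{FingerprintMatrix}.
#' @param cm heterozygous \linkS4class{CoinhibitionMatrix}.
#' @param pairSpecific passed to [structEnrichment()].
#' @return data.frame with gene_id, compound_id, the 20 feature
#'   columns, and label when supplied; sentinel flags are attached as
#'   the \code{"flags"} attribute.
#' @export
buildFeatureTable <- function(pairs, ds, annotations, calls, fp, cm,
                              pairSpecific = TRUE) {
    fd <- fdScores(ds)
    pv <- pValues(ds)
    stopifnot(all(pairs$gene_id %in% rownames(fd)))
    if (!all(pairs$compound_id %in% colnames(fd)))
        stop("pair references a compound absent from the dataset")
    freq <- sensitivityFrequencies(calls)
    hom <- stats::setNames(annotations$hom_rich_medium_fd,
                           annotations$gene_id)
    n <- nrow(pairs)
    feat <- matrix(0, n, 20L, dimnames = list(NULL, featureNames()))
    flags <- data.frame(missing_fd = logical(n), missing_pval = logical(n),
                        empty_ci = logical(n), small_ci = logical(n))
    for (r in seq_len(n)) {
        g <- pairs$gene_id[r]; cp <- pairs$compound_id[r]
        ratio <- fd[g, cp]; p <- pv[g, cp]
        flags$missing_fd[r] <- is.na(ratio)
        flags$missing_pval[r] <- is.na(p)
        feat[r, "ratio"] <- if (is.na(ratio)) 0 else ratio
        feat[r, "pvalue"] <- if (is.na(p)) 1 else p
        feat[r, "genefreq"] <- freq$genefreq[[g]]
        feat[r, "drugfreq"] <- freq$drugfreq[[cp]]
        h <- hom[[g]]
        feat[r, "hompheno"] <- if (is.null(h) || is.na(h)) 0 else h
        se <- structEnrichment(g, calls, fp, cp,
                               pairSpecific = pairSpecific)
        flags$empty_ci[r] <- se$flag
        feat[r, "struct_enrichment"] <- se$rr
        feat[r, "struct_count"] <- structCount(g, cp, calls, fp)
        ss <- structSimilarityMean(g, calls, fp)
        flags$small_ci[r] <- ss$flag
        feat[r, "struct_similarity"] <- ss$value
        feat[r, 9:20] <- secondaryLigandFeatures(cp, g, cm, ds)
    }
    out <- data.frame(gene_id = pairs$gene_id,
                      compound_id = pairs$compound_id,
                      feat, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if ("label" %in% colnames(pairs)) out$label <- pairs$label
    attr(out, "flags") <- flags
    out
}
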