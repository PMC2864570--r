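#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Strain-by-condition fitness dataset
#'
#' Container for pooled deletion-strain fitness screens. Extends
#' \linkS4class{SummarizedExperiment} with two assays: \code{fd}, the
#' log2-ratio fitness-defect score (control over treatment abundance, so
#' sensitive strains score positive), and \code{pval}, the one-sided
#' P-value for sensitivity. Columns are screening conditions; the column
#' data carries \code{condition_id}, \code{compound_id},
#' \code{concentration} and \code{timepoint}, so several conditions may
#' map to the same compound. The \code{zygosity} slot records whether the
#' strains are heterozygous (HIP assay) or homozygous (HOP assay)
#' deletions.
#'
#' @slot zygosity character, either \code{"heterozygous"} or
#'   \code{"homozygous"}.
#' @seealso [FitnessDataset()] for construction, [collapseReplicates()],
#'   [significantCalls()]
#' @exportClass FitnessDataset
setClass("FitnessDataset",
    contains = "SummarizedExperiment",
    representation(zygosity = "character"))

setValidity("FitnessDataset", function(object) {
    msg <- character()
    if (length(object@zygosity) != 1L ||
        !object@zygosity %in% c("heterozygous", "homozygous"))
        msg <- c(msg, "zygosity must be 'heterozygous' or 'homozygous'")
    if (!all(c("fd", "pval") %in% assayNames(object)))
        msg <- c(msg, "assays 'fd' and 'pval' are required")
    else {
        p <- assay(object, "pval")
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "non-missing P-values must lie in [0, 1]")
    }
    if (!"compound_id" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'compound_id' column")
    else if (anyNA(colData(object)$compound_id))
        msg <- c(msg, "every condition must reference a compound id")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "condition ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Substructure fingerprint matrix
#'
#' Compound-by-motif matrix of substructure fingerprints (by default the
#' 554 PubChem SMILES/SMARTS substructure keys, numbered 327 through
#' 880). Three representations are distinguished: raw \code{binary}
#' presence bits, \code{idf} inverse-document-frequency weights, and
#' \code{idf_binarized} bits retained only for motifs whose IDF exceeds
#' a rarity threshold. The per-motif document counts (number of
#' compounds carrying each motif, computed from the original binary
#' bits) are carried through all representations.
#'
#' @slot bits numeric matrix, compounds in rows, motifs in columns.
#' @slot form character, one of \code{"binary"}, \code{"idf"},
#'   \code{"idf_binarized"}.
#' @slot docCounts integer vector, per-motif compound counts.
#' @seealso [FingerprintMatrix()], [idfTransform()], [binarizeIdf()],
#'   [structuralSimilarity()]
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
    representation(bits = "matrix", form = "character",
                   docCounts = "integer"))

setValidity("FingerprintMatrix", function(object) {
    msg <- character()
    if (!object@form %in% c("binary", "idf", "idf_binarized"))
        msg <- c(msg, "form must be binary, idf or idf_binarized")
    if (length(object@docCounts) != ncol(object@bits))
        msg <- c(msg, "docCounts length must equal motif count")
    if (any(object@docCounts < 0) || any(object@docCounts > nrow(object@bits)))
        msg <- c(msg, "docCounts must lie in [0, number of compounds]")
    if (is.null(rownames(object@bits)))
        msg <- c(msg, "compound ids (rownames) are required")
    if (object@form %in% c("binary", "idf_binarized") &&
        !all(object@bits %in% c(0, 1)))
        msg <- c(msg, "binary representations must contain only 0/1")
    if (length(msg)) msg else TRUE
})

#' Gene-gene co-fitness matrix
#'
#' Symmetric matrix of pairwise profile-similarity scores between gene
#' deletion strains, computed across screening conditions. Entries are
#' missing where the pairwise-complete overlap falls below the
#' minimum-overlap floor.
#'
#' @slot scores symmetric numeric matrix, genes in rows and columns.
#' @slot metric character, one of pearson, spearman, euclidean,
#'   binary_cosine. Euclidean distances are stored negated so that
#'   larger always means more similar.
#' @slot scoreType character, the score type the profiles were taken
#'   from (log2ratio, zscore, pvalue, log_pvalue).
#' @slot minOverlap numeric, minimum number of shared non-missing
#'   conditions per pair.
#' @seealso [cofitnessMatrix()], [cofitnessThreshold()]
#' @exportClass CofitnessMatrix
setClass("CofitnessMatrix",
    representation(scores = "matrix", metric = "character",
                   scoreType = "character", minOverlap = "numeric"))

#' Compound-compound co-inhibition matrix
#'
#' Symmetric matrix of Pearson correlations of the chemical response
#' (fitness-defect profile across gene deletion strains) for every pair
#' of compounds.
#'
#' @slot scores symmetric numeric correlation matrix, compounds in rows
#'   and columns.
#' @slot zygosity character, the assay the profiles came from.
#' @slot minOverlap numeric, minimum shared non-missing genes per pair.
#' @seealso [coinhibitionMatrix()]
#' @exportClass CoinhibitionMatrix
setClass("CoinhibitionMatrix",
    representation(scores = "matrix", zygosity = "character",
                   minOverlap = "numeric"))

.checkSymmetric <- function(object) {
    s <- object@scores
    if (nrow(s) != ncol(s) || !identical(rownames(s), colnames(s)))
        return("score matrix must be square with matching dimnames")
    d <- abs(s - t(s))
    if (any(d > 1e-8, na.rm = TRUE))
        return("score matrix must be symmetric")
    TRUE
}
setValidity("CofitnessMatrix", .checkSymmetric)
setValidity("CoinhibitionMatrix", .checkSymmetric)

#' Precision-recall curve
#'
#' One point per distinct score threshold: pairs (or examples) scoring
#' at or above the threshold are called positive and compared against
#' the truth set, giving TP, FP, FN, precision and recall. \code{auc}
#' holds the area under the precision-coverage curve (trapezoidal, up to
#' the maximum achieved recall).
#'
#' @slot points data.frame with columns threshold, tp, fp, fn,
#'   precision, recall.
#' @slot auc numeric area under the precision-coverage curve.
#' @seealso [precisionRecallCurve()], [aucPrecisionCoverage()]
#' @exportClass PRCurve
setClass("PRCurve",
    representation(points = "data.frame", auc = "numeric"))

#' Decision stump model
#'
#' Single-feature, single-threshold classifier: the baseline model for
#' drug-target prediction. \code{polarity} +1 predicts positive above
#' the threshold, -1 below it.
#'
#' @slot feature character, the selected feature name.
#' @slot threshold numeric split point.
#' @slot polarity numeric, +1 or -1.
#' @slot features character, the feature names the model was trained on.
#' @seealso [trainClassifier()]
#' @exportClass StumpModel
setClass("StumpModel",
    representation(feature = "character", threshold = "numeric",
                   polarity = "numeric", features = "character"))

#' Random forest model
#'
#' Ensemble of CART-style decision trees grown on bootstrap resamples;
#' each node considers floor(sqrt(M)) + 1 randomly drawn candidate
#' features. The ensemble decision is the mode of the tree votes and the
#' confidence is the fraction of trees voting positive.
#'
#' @slot trees list of recursive tree structures.
#' @slot nTrees integer number of trees (10 by default).
#' @slot mtry integer per-node candidate feature count.
#' @slot features character, feature names the model was trained on.
#' @seealso [trainClassifier()], [crossValidate()]
#' @exportClass ForestModel
setClass("ForestModel",
    representation(trees = "list", nTrees = "integer", mtry = "integer",
                   features = "character"))
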