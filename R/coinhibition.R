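#' Compound-compound co-inhibition matrix
#'
#' Co-inhibition of a compound pair is the Pearson correlation of the
#' chemical response (fitness-defect profile) across all gene deletion
#' strains. The dataset should first be collapsed to one column per
#' compound with [collapseReplicates()]. Pairwise statistics use genes
#' observed for both compounds; pairs below the overlap floor are
#' missing.
#'
#' @param ds a replicate-collapsed \linkS4class{FitnessDataset}.
#' @param minOverlap minimum shared non-missing genes per pair.
#' @return a \linkS4class{CoinhibitionMatrix}.
#' @export
coinhibitionMatrix <- function(ds, minOverlap = 10) {
    comp <- compoundIds(ds)
    if (anyDuplicated(comp))
        stop("collapse replicates first: several conditions map to one compound")
    if (length(comp) < 2L) stop("need at least two compounds")
    X <- t(fdScores(ds))          # compounds x genes
    rownames(X) <- comp
    S <- stats::cor(t(X), use = "pairwise.complete.obs")
    S <- .applyOverlapFloor(S, X, minOverlap)
    diag(S) <- 1
    dimnames(S) <- list(comp, comp)
    new("CoinhibitionMatrix", scores = S, zygosity = zygosity(ds),
        minOverlap = minOverlap)
}

#' @rdname scores
#' @export
setMethod("scores", "CoinhibitionMatrix", function(x) x@scores)

setMethod("show", "CoinhibitionMatrix", function(object) {
    cat(sprintf("CoinhibitionMatrix: %d compounds (%s), minOverlap=%g\n",
        nrow(object@scores), object@zygosity, object@minOverlap))
})

#' Inverse-document-frequency weighting of fingerprint bits
#'
#' Converts binary substructure indicators to IDF weights from text
#' mining: a compound carrying motif m_i scores ln(|C| / c_i), where
#' |C| is the number of compounds and c_i the number of compounds
#' containing the motif; compounds lacking the motif score 0. Rare
#' motifs therefore get large weights and ubiquitous motifs weight
#' ln(1) = 0. Motifs absent from every compound stay 0 everywhere.
#'
#' @param fp a binary \linkS4class{FingerprintMatrix}.
#' @return an idf-form \linkS4class{FingerprintMatrix}.
#' @export
idfTransform <- function(fp) {
    if (fingerprintForm(fp) != "binary")
        stop("idfTransform expects a binary fingerprint matrix")
    bits <- scores(fp)
    counts <- fp@docCounts
    idf <- ifelse(counts > 0, log(nrow(bits) / counts), 0)
    weighted <- sweep(bits, 2, idf, "*")
    new("FingerprintMatrix", bits = weighted, form = "idf",
        docCounts = counts)
}

#' Binarize IDF-weighted fingerprints at a rarity threshold
#'
#' Keeps a bit only where the compound carries the motif and the
#' motif's IDF strictly exceeds the threshold (IDF > 2.5 by default).
#' Commonly occurring substructures (IDF at or below the threshold) are
#' always 0, so bits are only ever removed, never added.
#'
#' @param fp an idf-form \linkS4class{FingerprintMatrix}.
#' @param idfThreshold rarity threshold (strict).
#' @return an idf_binarized \linkS4class{FingerprintMatrix}.
#' @export
binarizeIdf <- function(fp, idfThreshold = 2.5) {
    if (fingerprintForm(fp) != "idf")
        stop("binarizeIdf expects an idf-form fingerprint matrix")
    bits <- (scores(fp) > idfThreshold) * 1
    new("FingerprintMatrix", bits = bits, form = "idf_binarized",
        docCounts = fp@docCounts)
}

.binaryMetrics <- c("tanimoto", "dice", "hamming")

#' Structural similarity of two compounds
#'
#' Computes a similarity (or distance) between two fingerprint rows.
#' Binary metrics (Tanimoto/Jaccard, Dice, Hamming) require a binary or
#' idf_binarized representation; Tanimoto and Dice use only the present
#' substructures (the 'on' bits) and are defined as 0 when both bit
#' sets are empty. Hamming, Euclidean and city-block are distances
#' (larger = less similar); the remaining metrics are similarities.
#'
#' @param fp a \linkS4class{FingerprintMatrix}.
#' @param a,b compound ids.
#' @param metric one of tanimoto, dice, hamming, cosine, pearson,
#'   spearman, euclidean, kendall, cityblock.
#' @return numeric scalar.
#' @export
structuralSimilarity <- function(fp, a, b,
                                 metric = c("tanimoto", "dice", "hamming",
                                            "cosine", "pearson", "spearman",
                                            "euclidean", "kendall",
                                            "cityblock")) {
    metric <- match.arg(metric)
    bits <- scores(fp)
    if (!all(c(a, b) %in% rownames(bits)))
        stop("unknown compound id")
    if (metric %in% .binaryMetrics &&
        !fingerprintForm(fp) %in% c("binary", "idf_binarized"))
        stop(metric, " requires a binary fingerprint representation")
    x <- bits[a, ]; y <- bits[b, ]
    switch(metric,
        tanimoto = {
            inter <- sum(x == 1 & y == 1)
            uni <- sum(x == 1 | y == 1)
            if (uni == 0) 0 else inter / uni
        },
        dice = {
            inter <- sum(x == 1 & y == 1)
            tot <- sum(x == 1) + sum(y == 1)
            if (tot == 0) 0 else 2 * inter / tot
        },
        hamming = sum(x != y),
        cosine = {
            denom <- sqrt(sum(x^2) * sum(y^2))
            if (denom == 0) 0 else sum(x * y) / denom
        },
        pearson = stats::cor(x, y),
        spearman = stats::cor(x, y, method = "spearman"),
        kendall = stats::cor(x, y, method = "kendall"),
        euclidean = sqrt(sum((x - y)^2)),
        cityblock = sum(abs(x - y)))
}

#' All pairwise Tanimoto similarities
#'
#' Vectorized Tanimoto (intersection over union of 'on' bits) for every
#' compound pair; the empty-versus-empty case is 0.
#'
#' @param fp a binary or idf_binarized \linkS4class{FingerprintMatrix}.
#' @return symmetric similarity matrix.
#' @export
tanimotoMatrix <- function(fp) {
    if (!fingerprintForm(fp) %in% c("binary", "idf_binarized"))
        stop("tanimotoMatrix requires a binary fingerprint representation")
    B <- scores(fp)
    inter <- B %*% t(B)
    ones <- rowSums(B)
    uni <- outer(ones, ones, "+") - inter
    out <- ifelse(uni > 0, inter / uni, 0)
    diag(out)[ones == 0] <- 0
    dimnames(out) <- list(rownames(B), rownames(B))
    out
}

#' Shared therapeutic class at ATC level 3
#'
#' Two compounds are co-therapeutic when any of their 7-character WHO
#' ATC codes agree on the level-3 prefix (the first four characters,
#' encoding the therapeutic/pharmacological subgroup). Compounds with
#' empty ATC annotation are never co-therapeutic.
#'
#' @param compounds compound annotation data.frame.
#' @param a,b compound ids.
#' @return logical scalar.
#' @export
sharedTherapeutic <- function(compounds, a, b) {
    codes <- atcCodes(compounds)
    if (!all(c(a, b) %in% names(codes)))
        stop("unknown compound id")
    ca <- codes[[a]]; cb <- codes[[b]]
    if (!length(ca) || !length(cb)) return(FALSE)
    .checkAtc(c(ca, cb))
    any(substr(ca, 1, 4) %in% substr(cb, 1, 4))
}

#' Structure / therapy / co-inhibition cross-tabulation
#'
#' Among compound pairs that are positively co-inhibiting (correlation
#' strictly above 0) and share a therapeutic class, what fraction lacks
#' measurable structural similarity (Tanimoto below the cutoff)? Also
#' reports the full 2x2x2 tabulation over the three binary pair
#' properties. On the published datasets this fraction was 74%
#' (heterozygous) and 90% (homozygous).
#'
#' @param cm a \linkS4class{CoinhibitionMatrix}.
#' @param fp a binary or idf_binarized \linkS4class{FingerprintMatrix}
#'   (typically the IDF > 2.5 binarized form).
#' @param compounds compound annotation data.frame.
#' @param tanimotoCutoff structural-similarity cutoff (pairs strictly
#'   below are 'not co-structural').
#' @return list with \code{nCoinhibCotherapeutic},
#'   \code{fractionBelowCutoff}, \code{table} (2x2x2 array) and the
#'   per-pair data.frame \code{pairs}.
#' @export
structureTherapySummary <- function(cm, fp, compounds,
                                    tanimotoCutoff = 0.2) {
    common <- Reduce(intersect, list(rownames(scores(cm)),
                                     rownames(scores(fp)),
                                     compounds$compound_id))
    if (length(common) < 2L) stop("fewer than two compounds in common")
    S <- scores(cm)[common, common]
    Tm <- tanimotoMatrix(fp)[common, common]
    codes <- atcCodes(compounds)
    lvl3 <- lapply(codes[common], function(x) unique(substr(x, 1, 4)))
    idx <- which(upper.tri(S), arr.ind = TRUE)
    coin <- S[idx]
    tan <- Tm[idx]
    cother <- mapply(function(i, j) {
        a <- lvl3[[i]]; b <- lvl3[[j]]
        length(a) > 0 && length(b) > 0 && any(a %in% b)
    }, idx[, 1], idx[, 2])
    pairs <- data.frame(compound1 = common[idx[, 1]],
                        compound2 = common[idx[, 2]],
                        coinhibition = coin, tanimoto = tan,
                        co_inhibiting = !is.na(coin) & coin > 0,
                        co_therapeutic = cother,
                        co_structural = tan >= tanimotoCutoff,
                        stringsAsFactors = FALSE)
    sel <- pairs$co_inhibiting & pairs$co_therapeutic
    tab <- table(co_inhibiting = pairs$co_inhibiting,
                 co_therapeutic = pairs$co_therapeutic,
                 co_structural = pairs$co_structural)
    list(nCoinhibCotherapeutic = sum(sel),
         fractionBelowCutoff = if (sum(sel) > 0)
             mean(pairs$tanimoto[sel] < tanimotoCutoff) else NA_real_,
         table = tab,
         pairs = pairs)
}
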