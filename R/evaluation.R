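#' Precision-recall curve over a score threshold sweep
#'
#' At every distinct observed score threshold t, pairs (or examples)
#' scoring at least t are called positive; TP, FP and FN are counted
#' against the truth labels within the universe. Examples with missing
#' scores are treated as scoring below every threshold (they only ever
#' contribute false negatives). Recall is non-decreasing as the
#' threshold falls.
#'
#' @param score numeric vector of scores over the universe (NA
#'   allowed).
#' @param label logical vector: TRUE for members of the truth set.
#' @return a \linkS4class{PRCurve}.
#' @export
precisionRecallCurve <- function(score, label) {
    stopifnot(length(score) == length(label))
    label <- as.logical(label)
    nTruth <- sum(label)
    if (nTruth == 0L) stop("truth set is empty")
    ok <- !is.na(score)
    s <- score[ok]; y <- label[ok]
    o <- order(s, decreasing = TRUE)
    s <- s[o]; y <- y[o]
    cumTp <- cumsum(y)
    cumFp <- cumsum(!y)
    last <- !duplicated(s, fromLast = TRUE)   # last index of each threshold
    thr <- s[last]
    tp <- cumTp[last]
    fp <- cumFp[last]
    fn <- nTruth - tp
    points <- data.frame(threshold = thr, tp = tp, fp = fp, fn = fn,
                         precision = ifelse(tp + fp > 0, tp / (tp + fp),
                                            NA_real_),
                         recall = tp / nTruth)
    rownames(points) <- NULL
    curve <- new("PRCurve", points = points, auc = NA_real_)
    curve@auc <- aucPrecisionCoverage(curve)
    curve
}

#' @rdname PRCurve-class
#' @export
setMethod("prPoints", "PRCurve", function(x) x@points)

setMethod("show", "PRCurve", function(object) {
    cat(sprintf("PRCurve: %d thresholds, AUC (precision-coverage) = %.4f\n",
        nrow(object@points), object@auc))
})

#' Area under the precision-coverage curve
#'
#' Trapezoidal area over recall from 0 to the maximum achieved recall,
#' with precision linearly interpolated between achieved points and no
#' extrapolation beyond the maximum recall. The initial segment from
#' recall 0 to the first achieved point uses that point's precision.
#' Thresholds achieving the same recall are collapsed to their best
#' precision.
#'
#' @param curve a \linkS4class{PRCurve}.
#' @return numeric area.
#' @export
aucPrecisionCoverage <- function(curve) {
    pts <- prPoints(curve)
    pts <- pts[!is.na(pts$precision) & pts$recall > 0, ]
    if (!nrow(pts)) return(0)
    best <- stats::aggregate(precision ~ recall, pts, max)
    best <- best[order(best$recall), ]
    r <- best$recall; p <- best$precision
    area <- r[1] * p[1]
    if (length(r) > 1L)
        area <- area + sum(diff(r) * (utils::head(p, -1) + p[-1]) / 2)
    area
}

#' Evaluate pair scores against a reference network
#'
#' Builds the PR curve of a co-fitness (or any pairwise score) matrix
#' against reference functional links. The universe is every unordered
#' gene pair present in the score matrix (optionally restricted); a
#' dataset is not penalized for genes it never measured.
#'
#' @param cm a \linkS4class{CofitnessMatrix} (or any object with a
#'   [scores()] matrix).
#' @param reference canonical pair data.frame of positive links.
#' @param genes optional restriction of the gene universe.
#' @return a \linkS4class{PRCurve}.
#' @export
networkPrCurve <- function(cm, reference, genes = NULL) {
    S <- scores(cm)
    if (!is.null(genes)) {
        genes <- intersect(genes, rownames(S))
        S <- S[genes, genes, drop = FALSE]
    }
    idx <- which(upper.tri(S), arr.ind = TRUE)
    score <- S[idx]
    key <- paste(pmin(rownames(S)[idx[, 1]], rownames(S)[idx[, 2]]),
                 pmax(rownames(S)[idx[, 1]], rownames(S)[idx[, 2]]),
                 sep = "\r")
    refKey <- paste(reference$gene1, reference$gene2, sep = "\r")
    precisionRecallCurve(score, key %in% refKey)
}

#' Per-process evaluation of a co-fitness network
#'
#' Splits the reference network into per-process sub-networks: a gene
#' pair belongs to a process when both genes carry that process label.
#' For each process the universe is all labeled pairs present in the
#' score matrix, the truth the reference edges among them, and the
#' reported value the area under the precision-coverage curve.
#' Processes whose truth set is empty are reported NA.
#'
#' @param cm a \linkS4class{CofitnessMatrix}.
#' @param reference canonical pair data.frame of positive links.
#' @param annotations gene-annotation data.frame (column
#'   \code{processes}).
#' @return data.frame with columns process, n_genes, n_pairs, n_truth,
#'   auc.
#' @export
functionSpecificEvaluation <- function(cm, reference, annotations) {
    procs <- geneProcesses(annotations)
    labels <- sort(unique(unlist(procs)))
    labels <- labels[nzchar(labels)]
    if (!length(labels)) stop("no process labels in the annotations")
    S <- scores(cm)
    refKey <- paste(reference$gene1, reference$gene2, sep = "\r")
    rows <- lapply(labels, function(p) {
        genes <- names(procs)[vapply(procs, function(x) p %in% x, TRUE)]
        genes <- intersect(genes, rownames(S))
        if (length(genes) < 2L)
            return(data.frame(process = p, n_genes = length(genes),
                              n_pairs = 0L, n_truth = 0L, auc = NA_real_))
        sub <- S[genes, genes, drop = FALSE]
        idx <- which(upper.tri(sub), arr.ind = TRUE)
        key <- paste(pmin(genes[idx[, 1]], genes[idx[, 2]]),
                     pmax(genes[idx[, 1]], genes[idx[, 2]]), sep = "\r")
        truth <- key %in% refKey
        auc <- if (any(truth))
            precisionRecallCurve(sub[idx], truth)@auc else NA_real_
        data.frame(process = p, n_genes = length(genes),
                   n_pairs = nrow(idx), n_truth = sum(truth), auc = auc)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
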