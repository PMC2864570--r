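## Pairwise-complete similarity helpers shared by co-fitness and
## co-inhibition. X is an entity-by-observation matrix; every pairwise
## statistic is computed over observations where both rows are
## non-missing, and pairs with fewer than minOverlap shared
## observations are reported missing.

.pairwiseOverlap <- function(X) {
    M <- (!is.na(X)) * 1
    M %*% t(M)
}

.pairwiseEuclidean <- function(X) {
    M <- (!is.na(X)) * 1
    X0 <- replace(X, is.na(X), 0)
    Sxy <- X0 %*% t(X0)
    Sx2 <- (X0^2) %*% t(M)   # sum of x^2 over shared support
    d2 <- Sx2 + t(Sx2) - 2 * Sxy
    d2[d2 < 0] <- 0          # numerical guard
    sqrt(d2)
}

.pairwiseCosine <- function(X) {
    M <- (!is.na(X)) * 1
    X0 <- replace(X, is.na(X), 0)
    Sxy <- X0 %*% t(X0)
    Sx2 <- (X0^2) %*% t(M)
    denom <- sqrt(Sx2 * t(Sx2))
    out <- Sxy / denom
    out[denom == 0] <- 0
    out
}

.applyOverlapFloor <- function(S, X, minOverlap) {
    n <- .pairwiseOverlap(X)
    S[n < minOverlap] <- NA_real_
    S
}

.scoreMatrix <- function(ds, scoreType) {
    switch(scoreType,
        log2ratio = fdScores(ds),
        zscore = {
            fd <- fdScores(ds)
            mu <- colMeans(fd, na.rm = TRUE)
            sd <- apply(fd, 2, stats::sd, na.rm = TRUE)
            sweep(sweep(fd, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
        },
        pvalue = pValues(ds),
        log_pvalue = {
            p <- pValues(ds)
            -log10(pmax(p, .Machine$double.xmin))
        },
        stop("unknown score type: ", scoreType))
}

#' Gene-gene co-fitness matrix
#'
#' Pairwise similarity of gene fitness profiles across conditions.
#' Four metrics are supported: Pearson correlation, Spearman rank
#' correlation, Euclidean distance (stored negated so larger always
#' means more similar) and the cosine of binary data discretized at a
#' log2-ratio cutoff of 0.5. Profiles can be taken from four score
#' types: the log2 ratio itself, per-condition z-scores, the P-value,
#' or -log10 P. Pairwise statistics use conditions where both genes are
#' observed; pairs with fewer than \code{minOverlap} shared conditions
#' are reported missing.
#'
#' @param ds a \linkS4class{FitnessDataset}.
#' @param metric one of \code{"pearson"}, \code{"spearman"},
#'   \code{"euclidean"}, \code{"binary_cosine"}.
#' @param scoreType one of \code{"log2ratio"}, \code{"zscore"},
#'   \code{"pvalue"}, \code{"log_pvalue"}.
#' @param minOverlap minimum shared non-missing conditions per pair.
#' @param binaryCutoff discretization cutoff for \code{binary_cosine}
#'   (fd > 0.5 by default).
#' @return a \linkS4class{CofitnessMatrix}.
#' @export
cofitnessMatrix <- function(ds, metric = c("pearson", "spearman",
                                           "euclidean", "binary_cosine"),
                            scoreType = c("log2ratio", "zscore", "pvalue",
                                          "log_pvalue"),
                            minOverlap = 10, binaryCutoff = 0.5) {
    metric <- match.arg(metric)
    scoreType <- match.arg(scoreType)
    if (ncol(ds) < minOverlap)
        stop("dataset has fewer conditions than minOverlap")
    X <- .scoreMatrix(ds, scoreType)
    S <- switch(metric,
        pearson = stats::cor(t(X), use = "pairwise.complete.obs"),
        spearman = stats::cor(t(X), use = "pairwise.complete.obs",
                              method = "spearman"),
        euclidean = -.pairwiseEuclidean(X),
        binary_cosine = {
            B <- (X > binaryCutoff) * 1
            .pairwiseCosine(B) |>
                `dimnames<-`(list(rownames(X), rownames(X)))
        })
    S <- .applyOverlapFloor(S, X, minOverlap)
    if (metric %in% c("pearson", "spearman")) diag(S) <- 1
    if (metric == "euclidean") diag(S) <- 0
    dimnames(S) <- list(rownames(X), rownames(X))
    new("CofitnessMatrix", scores = S, metric = metric,
        scoreType = scoreType, minOverlap = minOverlap)
}

#' @rdname scores
#' @export
setMethod("scores", "CofitnessMatrix", function(x) x@scores)

setMethod("show", "CofitnessMatrix", function(object) {
    cat(sprintf("CofitnessMatrix: %d genes, metric=%s, scoreType=%s, minOverlap=%g\n",
        nrow(object@scores), object@metric, object@scoreType,
        object@minOverlap))
})

.offDiagonal <- function(S) {
    S[upper.tri(S)]
}

#' Significance threshold for co-fitness scores
#'
#' Significant co-fitness is defined as scores more than three standard
#' deviations above the mean of all (unordered, off-diagonal) pair
#' scores, using the sample standard deviation. On the full published
#' heterozygous dataset this rule gave a Pearson threshold of 0.47.
#'
#' @param cm a \linkS4class{CofitnessMatrix}.
#' @param nSd number of standard deviations above the mean (3 = P <
#'   0.01 under a normal null).
#' @return numeric threshold (mean + nSd * SD).
#' @export
cofitnessThreshold <- function(cm, nSd = 3) {
    vals <- .offDiagonal(scores(cm))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L)
        stop("need at least two off-diagonal non-missing scores")
    mean(vals) + nSd * stats::sd(vals)
}

.pairScores <- function(cm, pairs) {
    S <- scores(cm)
    ok <- pairs$gene1 %in% rownames(S) & pairs$gene2 %in% rownames(S)
    S[cbind(pairs$gene1[ok], pairs$gene2[ok])]
}

#' Paralog co-fitness test
#'
#' Do duplicated (paralogous) gene pairs show higher-than-average
#' co-fitness? Compares the scores of annotated paralog pairs against
#' all other gene-pair scores with a Welch two-sample t-test.
#'
#' @param cm a \linkS4class{CofitnessMatrix}.
#' @param annotations gene-annotation data.frame (column
#'   \code{paralog_partner}).
#' @return list with \code{statistic}, \code{p.value},
#'   \code{meanParalog}, \code{meanBackground}, \code{nParalog}.
#' @export
paralogCofitnessTest <- function(cm, annotations) {
    has <- !is.na(annotations$paralog_partner)
    pairs <- canonicalPairs(data.frame(
        annotations$gene_id[has], annotations$paralog_partner[has]))
    S <- scores(cm)
    parScores <- .pairScores(cm, pairs)
    parScores <- parScores[!is.na(parScores)]
    all <- .offDiagonal(S)
    isPar <- matrix(FALSE, nrow(S), ncol(S), dimnames = dimnames(S))
    keep <- pairs$gene1 %in% rownames(S) & pairs$gene2 %in% rownames(S)
    isPar[cbind(pairs$gene1[keep], pairs$gene2[keep])] <- TRUE
    isPar[cbind(pairs$gene2[keep], pairs$gene1[keep])] <- TRUE
    bg <- S[upper.tri(S) & !isPar]
    bg <- bg[!is.na(bg)]
    if (length(parScores) < 2L || length(bg) < 2L)
        stop("need at least two paralog and two background pair scores")
    tt <- stats::t.test(parScores, bg)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         meanParalog = mean(parScores), meanBackground = mean(bg),
         nParalog = length(parScores))
}

#' Essential-partner fractions of significantly co-fit genes
#'
#' For every gene, its significantly co-fit partners are the genes whose
#' score exceeds the threshold; the per-gene statistic is the fraction
#' of those partners that are essential (missing when a gene has no
#' partners). The summary compares the mean fraction of essential query
#' genes against non-essential query genes (Welch t-test).
#'
#' @param cm a \linkS4class{CofitnessMatrix}.
#' @param annotations gene-annotation data.frame (column
#'   \code{essential}).
#' @param threshold co-fitness significance threshold, typically from
#'   [cofitnessThreshold()].
#' @return list with \code{perGene} (data.frame gene_id, essential,
#'   n_partners, fraction_essential), \code{meanEssential},
#'   \code{meanNonEssential} and \code{p.value}.
#' @export
essentialPartnerFractions <- function(cm, annotations, threshold) {
    S <- scores(cm)
    ess <- stats::setNames(annotations$essential, annotations$gene_id)
    genes <- intersect(rownames(S), names(ess))
    S <- S[genes, genes]
    diag(S) <- NA_real_
    partners <- S > threshold
    nPart <- rowSums(partners, na.rm = TRUE)
    essMat <- matrix(ess[genes], nrow = length(genes), ncol = length(genes),
                     byrow = TRUE)
    nEss <- rowSums(partners & essMat, na.rm = TRUE)
    frac <- ifelse(nPart > 0, nEss / nPart, NA_real_)
    perGene <- data.frame(gene_id = genes, essential = unname(ess[genes]),
                          n_partners = unname(nPart),
                          fraction_essential = unname(frac),
                          stringsAsFactors = FALSE)
    a <- frac[ess[genes] & !is.na(frac)]
    b <- frac[!ess[genes] & !is.na(frac)]
    pv <- if (length(a) >= 2L && length(b) >= 2L)
        stats::t.test(a, b)$p.value else NA_real_
    list(perGene = perGene,
         meanEssential = mean(a), meanNonEssential = mean(b),
         p.value = pv)
}

#' Co-complex co-fitness enrichment
#'
#' Do genes encoding subunits of the same protein complex show elevated
#' co-fitness? Compares within-complex pair scores against all other
#' pair scores with a Welch t-test.
#'
#' @param cm a \linkS4class{CofitnessMatrix}.
#' @param complexes named list of complex member gene vectors.
#' @return list with \code{meanWithin}, \code{meanBackground},
#'   \code{p.value}, \code{nWithin}.
#' @export
cocomplexEnrichment <- function(cm, complexes) {
    S <- scores(cm)
    eligible <- lapply(complexes, intersect, y = rownames(S))
    eligible <- eligible[vapply(eligible, length, 0L) >= 2L]
    if (!length(eligible)) stop("no complex has >= 2 members in the matrix")
    within <- matrix(FALSE, nrow(S), ncol(S), dimnames = dimnames(S))
    for (m in eligible) {
        idx <- t(utils::combn(m, 2L))
        within[idx] <- TRUE
        within[idx[, 2:1, drop = FALSE]] <- TRUE
    }
    w <- S[upper.tri(S) & within]
    b <- S[upper.tri(S) & !within]
    w <- w[!is.na(w)]; b <- b[!is.na(b)]
    pv <- if (length(w) >= 2L && length(b) >= 2L)
        stats::t.test(w, b)$p.value else NA_real_
    list(meanWithin = mean(w), meanBackground = mean(b),
         p.value = pv, nWithin = length(w))
}
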