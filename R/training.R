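#' Assemble a labeled training set from positive interactions
#'
#' Balanced mode draws a random negative set of the same size as the
#' positives on the same proteins and compounds, keeping every node's
#' connectivity degree identical to the positive set and forbidding any
#' pair that is a positive (a degree-preserving random bipartite
#' rewiring, repaired by seeded edge swaps; infeasibility after the
#' bounded retry budget is an error, never silently relaxed).
#' Unbalanced mode takes every protein-compound combination from the
#' positive set that is not itself a positive.
#'
#' @param positives interaction data.frame of positives (columns
#'   compound_id, gene_id).
#' @param mode \code{"balanced"} or \code{"unbalanced"}.
#' @param seed integer RNG seed (balanced mode).
#' @param maxSwaps swap-repair budget per restart.
#' @param maxRestarts independent restarts before giving up.
#' @return interaction data.frame with positives and negatives.
#' @export
assembleTrainingSet <- function(positives, mode = c("balanced", "unbalanced"),
                                seed = 1L, maxSwaps = 10000L,
                                maxRestarts = 20L) {
    mode <- match.arg(mode)
    if (!nrow(positives)) stop("positive set is empty")
    posKey <- paste(positives$compound_id, positives$gene_id, sep = "\r")
    if (mode == "unbalanced") {
        comb <- expand.grid(compound_id = unique(positives$compound_id),
                            gene_id = unique(positives$gene_id),
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
        key <- paste(comb$compound_id, comb$gene_id, sep = "\r")
        neg <- comb[!key %in% posKey, ]
    } else {
        neg <- withr::with_seed(seed, {
            .degreePreservingNegatives(positives$compound_id,
                                       positives$gene_id, posKey,
                                       maxSwaps, maxRestarts)
        })
    }
    neg$label <- "negative"
    neg$source <- paste0("sampled_", mode)
    pos <- positives[, c("compound_id", "gene_id")]
    pos$label <- "positive"
    pos$source <- if ("source" %in% colnames(positives))
        positives$source else "curated"
    out <- rbind(pos, neg[, c("compound_id", "gene_id", "label", "source")])
    rownames(out) <- NULL
    validateInteractions(out)
    out
}

## Configuration-model construction with swap repair: the compound
## stubs keep their order, the gene stubs are shuffled; edges that
## duplicate each other or hit a positive are repaired by swapping gene
## endpoints with random partner edges.
.degreePreservingNegatives <- function(compounds, genes, posKey,
                                       maxSwaps, maxRestarts) {
    m <- length(compounds)
    for (restart in seq_len(maxRestarts)) {
        g <- sample(genes)
        bad <- .invalidEdges(compounds, g, posKey)
        swaps <- 0L
        while (length(bad) && swaps < maxSwaps) {
            i <- bad[sample.int(length(bad), 1L)]
            j <- sample.int(m, 1L)
            gi <- g[i]; g[i] <- g[j]; g[j] <- gi
            swaps <- swaps + 1L
            bad <- .invalidEdges(compounds, g, posKey)
        }
        if (!length(bad))
            return(data.frame(compound_id = compounds, gene_id = g,
                              stringsAsFactors = FALSE))
    }
    stop("could not realize a degree-preserving negative set ",
         "disjoint from the positives (degree sequence may be infeasible)")
}

.invalidEdges <- function(compounds, genes, posKey) {
    key <- paste(compounds, genes, sep = "\r")
    which(key %in% posKey | duplicated(key) | duplicated(key, fromLast = TRUE))
}

## ---- decision stump -------------------------------------------------------

.featureMatrix <- function(table, features = NULL) {
    if (is.null(features)) features <- intersect(featureNames(),
                                                 colnames(table))
    X <- as.matrix(table[, features, drop = FALSE])
    storage.mode(X) <- "double"
    X
}

.labels01 <- function(table) {
    as.integer(table$label == "positive")
}

.trainStump <- function(X, y) {
    bestErr <- Inf; best <- NULL
    n <- length(y)
    for (j in seq_len(ncol(X))) {
        x <- X[, j]
        cuts <- sort(unique(x))
        thr <- if (length(cuts) > 1L)
            (utils::head(cuts, -1) + cuts[-1]) / 2 else cuts - 0.5
        for (t in thr) {
            predPos <- x > t
            errPlus <- sum(predPos != (y == 1L))
            errMinus <- n - errPlus
            if (errPlus < bestErr) {
                bestErr <- errPlus
                best <- list(j = j, t = t, pol = 1)
            }
            if (errMinus < bestErr) {
                bestErr <- errMinus
                best <- list(j = j, t = t, pol = -1)
            }
        }
    }
    new("StumpModel", feature = colnames(X)[best$j], threshold = best$t,
        polarity = best$pol, features = colnames(X))
}

## ---- CART trees with Gini impurity ----------------------------------------

.gini <- function(pos, n) {
    if (n == 0) return(0)
    p <- pos / n
    2 * p * (1 - p)
}

.bestSplit <- function(X, y, candidates, minLeaf) {
    n <- length(y)
    parent <- .gini(sum(y), n)
    best <- NULL; bestImp <- parent - 1e-12
    for (j in candidates) {
        x <- X[, j]
        o <- order(x)
        xs <- x[o]; ys <- y[o]
        cumPos <- cumsum(ys)
        distinct <- which(diff(xs) > 0)       # split after these positions
        if (!length(distinct)) next
        valid <- distinct[distinct >= minLeaf & (n - distinct) >= minLeaf]
        if (!length(valid)) next
        nl <- valid
        posL <- cumPos[valid]
        gl <- 2 * (posL / nl) * (1 - posL / nl)
        nr <- n - nl
        posR <- sum(y) - posL
        gr <- 2 * (posR / nr) * (1 - posR / nr)
        imp <- (nl * gl + nr * gr) / n
        k <- which.min(imp)
        if (imp[k] < bestImp) {
            bestImp <- imp[k]
            best <- list(j = j, t = (xs[valid[k]] + xs[valid[k] + 1L]) / 2)
        }
    }
    best
}

.growTree <- function(X, y, mtry, minLeaf = 2L) {
    n <- length(y)
    pos <- sum(y)
    if (pos == 0L || pos == n || n < 2L * minLeaf)
        return(list(type = "leaf", prob = pos / n, n = n))
    candidates <- sample.int(ncol(X), min(mtry, ncol(X)))
    split <- .bestSplit(X, y, candidates, minLeaf)
    if (is.null(split))
        return(list(type = "leaf", prob = pos / n, n = n))
    left <- X[, split$j] <= split$t
    list(type = "split",
         feature = colnames(X)[split$j], threshold = split$t,
         left = .growTree(X[left, , drop = FALSE], y[left], mtry, minLeaf),
         right = .growTree(X[!left, , drop = FALSE], y[!left], mtry,
                           minLeaf))
}

.predictTreeRow <- function(node, x) {
    while (node$type == "split") {
        node <- if (x[[node$feature]] <= node$threshold) node$left
                else node$right
    }
    node$prob
}

#' Train a drug-target classifier
#'
#' Two algorithms: the decision-stump baseline (the single feature and
#' threshold minimizing training misclassification) and a random
#' forest of \code{nTrees} CART-style trees (Gini impurity, grown to
#' purity with a minimum leaf size of 2) on bootstrap resamples, each
#' node drawing floor(sqrt(M)) + 1 candidate features from the M
#' available. The forest decision is the mode of the tree votes; its
#' confidence is the fraction of positive votes, so confidences are
#' multiples of 1/nTrees.
#'
#' @param table labeled feature table from [buildFeatureTable()] (a
#'   \code{label} column with values positive/negative).
#' @param algorithm \code{"stump"} or \code{"random_forest"}.
#' @param features optional feature subset (defaults to all feature
#'   columns present).
#' @param nTrees forest size (10).
#' @param seed integer RNG seed (forest bootstraps and feature
#'   subsampling).
#' @return a \linkS4class{StumpModel} or \linkS4class{ForestModel}.
#' @export
trainClassifier <- function(table, algorithm = c("stump", "random_forest"),
                            features = NULL, nTrees = 10L, seed = 1L) {
    algorithm <- match.arg(algorithm)
    X <- .featureMatrix(table, features)
    y <- .labels01(table)
    if (length(unique(y)) < 2L)
        stop("training data must contain both classes")
    if (algorithm == "stump") return(.trainStump(X, y))
    mtry <- as.integer(floor(sqrt(ncol(X))) + 1L)
    trees <- withr::with_seed(seed, {
        lapply(seq_len(nTrees), function(i) {
            idx <- sample.int(nrow(X), replace = TRUE)
            .growTree(X[idx, , drop = FALSE], y[idx], mtry)
        })
    })
    new("ForestModel", trees = trees, nTrees = as.integer(nTrees),
        mtry = mtry, features = colnames(X))
}

#' @describeIn trainClassifier Forest predictions. \code{type =
#'   "confidence"} returns the fraction of trees voting positive (a
#'   tree votes positive when its leaf's positive fraction exceeds
#'   0.5); \code{type = "decision"} returns the mode of the votes, with
#'   the 0.5 tie resolved negative.
#' @param object a fitted model.
#' @param newdata feature table to score.
#' @param type \code{"confidence"} or \code{"decision"}.
#' @export
setMethod("predict", "ForestModel",
    function(object, newdata, type = c("confidence", "decision")) {
    type <- match.arg(type)
    X <- .featureMatrix(newdata, object@features)
    votes <- vapply(object@trees, function(tr)
        apply(X, 1, function(row) .predictTreeRow(tr, row) > 0.5),
        logical(nrow(X)))
    votes <- matrix(votes, nrow = nrow(X))
    conf <- rowMeans(votes)
    if (type == "confidence") conf else conf > 0.5
})

#' @describeIn trainClassifier Stump predictions. \code{type =
#'   "confidence"} returns the polarity-oriented value of the selected
#'   feature (a threshold sweep over it traces the stump's
#'   precision-recall curve); \code{type = "decision"} applies the
#'   fitted threshold.
#' @export
setMethod("predict", "StumpModel",
    function(object, newdata, type = c("confidence", "decision")) {
    type <- match.arg(type)
    x <- newdata[[object@feature]] * object@polarity
    if (type == "confidence") x
    else x > object@threshold * object@polarity
})

## ---- cross-validation -----------------------------------------------------

#' Stratified k-fold cross-validation with pooled precision-recall
#'
#' Splits the labeled pairs into k stratified folds (seeded), trains on
#' k-1 folds, scores the held-out fold, pools all held-out confidences
#' and sweeps every distinct confidence threshold into a
#' precision-recall curve.
#'
#' @inheritParams trainClassifier
#' @param k number of folds (10).
#' @return list with \code{curve} (\linkS4class{PRCurve}), \code{auc}
#'   and \code{scores} (per-pair held-out confidences with labels and
#'   fold ids).
#' @export
crossValidate <- function(table, algorithm = c("stump", "random_forest"),
                          k = 10L, seed = 1L, features = NULL,
                          nTrees = 10L) {
    algorithm <- match.arg(algorithm)
    y <- .labels01(table)
    if (min(table(y)) < k)
        stop("k exceeds the size of the smaller class")
    fold <- integer(length(y))
    withr::with_seed(seed, {
        for (cls in c(0L, 1L)) {
            idx <- sample(which(y == cls))
            fold[idx] <- rep(seq_len(k), length.out = length(idx))
        }
    })
    conf <- numeric(length(y))
    for (f in seq_len(k)) {
        train <- table[fold != f, , drop = FALSE]
        test <- table[fold == f, , drop = FALSE]
        model <- trainClassifier(train, algorithm, features = features,
                                 nTrees = nTrees, seed = seed + f)
        conf[fold == f] <- predict(model, test, type = "confidence")
    }
    curve <- precisionRecallCurve(conf, y == 1L)
    list(curve = curve, auc = curve@auc,
         scores = data.frame(gene_id = table$gene_id,
                             compound_id = table$compound_id,
                             label = table$label,
                             confidence = conf, fold = fold,
                             stringsAsFactors = FALSE))
}

#' Single-feature ablation of the forest
#'
#' Re-runs cross-validation with each feature removed in turn and
#' reports the drop in precision-coverage AUC relative to the full
#' model, quantifying each feature's contribution.
#'
#' @inheritParams crossValidate
#' @return data.frame with columns feature, auc, drop; the attribute
#'   \code{"fullAuc"} holds the all-features AUC.
#' @export
featureAblation <- function(table, k = 10L, seed = 1L, nTrees = 10L) {
    feats <- intersect(featureNames(), colnames(table))
    full <- crossValidate(table, "random_forest", k = k, seed = seed,
                          features = feats, nTrees = nTrees)$auc
    rows <- lapply(feats, function(f) {
        auc <- crossValidate(table, "random_forest", k = k, seed = seed,
                             features = setdiff(feats, f),
                             nTrees = nTrees)$auc
        data.frame(feature = f, auc = auc, drop = full - auc,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "fullAuc") <- full
    out
}

## ---- prediction filtering and calibration ---------------------------------

#' Filter top predictions for experimental follow-up
#'
#' Retains predicted (gene, compound) interactions passing all five
#' criteria used to nominate pairs for overexpression testing: the
#' gene is essential or shows a rich-medium homozygous fitness defect;
#' the prediction confidence is at least 0.7; the heterozygous fitness
#' defect is high (log ratio at least 5); the compound is not a
#' frequently predicted interactor (its predicted-positive count does
#' not fall in the top promiscuity decile); and the gene and compound
#' are reciprocal top-ten sensitivity hits of each other.
#'
#' @param predictions data.frame with gene_id, compound_id, confidence.
#' @param ds replicate-collapsed heterozygous
#'   \linkS4class{FitnessDataset}.
#' @param annotations gene-annotation data.frame.
#' @param confidenceCutoff minimum confidence (inclusive).
#' @param fdCutoff minimum heterozygous log2-ratio (inclusive).
#' @param homFdCutoff rich-medium homozygous defect counting as a
#'   phenotype.
#' @param promiscuityQuantile compounds whose predicted-positive count
#'   strictly exceeds this quantile are considered frequent
#'   interactors.
#' @param topN reciprocity depth (10).
#' @return the filtered data.frame with per-criterion logical columns.
#' @export
filterTopPredictions <- function(predictions, ds, annotations,
                                 confidenceCutoff = 0.7, fdCutoff = 5,
                                 homFdCutoff = 0.5,
                                 promiscuityQuantile = 0.9, topN = 10L) {
    fd <- fdScores(ds)
    ess <- stats::setNames(annotations$essential, annotations$gene_id)
    hom <- stats::setNames(annotations$hom_rich_medium_fd,
                           annotations$gene_id)
    posCount <- table(predictions$compound_id[predictions$confidence > 0.5])
    counts <- stats::setNames(rep(0, length(unique(predictions$compound_id))),
                              unique(predictions$compound_id))
    counts[names(posCount)] <- as.numeric(posCount)
    cutoffCount <- stats::quantile(counts, promiscuityQuantile, names = FALSE)

    rankTies <- function(v, ids) ids[order(-v, ids)]
    topGenes <- lapply(colnames(fd), function(cp) {
        v <- fd[, cp]; v[is.na(v)] <- -Inf
        utils::head(rankTies(v, rownames(fd)), topN)
    })
    names(topGenes) <- colnames(fd)
    topCompounds <- lapply(rownames(fd), function(g) {
        v <- fd[g, ]; v[is.na(v)] <- -Inf
        utils::head(rankTies(v, colnames(fd)), topN)
    })
    names(topCompounds) <- rownames(fd)

    g <- predictions$gene_id; cp <- predictions$compound_id
    fdVal <- fd[cbind(g, cp)]
    crit <- data.frame(
        gene_phenotype = ess[g] |
            (!is.na(hom[g]) & hom[g] >= homFdCutoff),
        confident = predictions$confidence >= confidenceCutoff,
        high_fd = !is.na(fdVal) & fdVal >= fdCutoff,
        not_promiscuous = counts[cp] <= cutoffCount,
        reciprocal = mapply(function(gi, ci)
            gi %in% topGenes[[ci]] && ci %in% topCompounds[[gi]], g, cp))
    crit$gene_phenotype[is.na(crit$gene_phenotype)] <- FALSE
    keep <- Reduce(`&`, crit)
    out <- cbind(predictions, crit)[keep, ]
    rownames(out) <- NULL
    out
}

#' Optical-density calibration for growth curves
#'
#' Plate-reader optical densities are non-linear in cell number at
#' high density; the calibration maps a measured OD to a 'real' OD via
#' real = -1.0543 + 12.2716 x measured.
#'
#' @param measured non-negative measured OD (vectorized).
#' @return calibrated OD values.
#' @export
calibrateOD <- function(measured) {
    if (any(measured < 0, na.rm = TRUE))
        stop("measured OD must be non-negative")
    -1.0543 + 12.2716 * measured
}
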