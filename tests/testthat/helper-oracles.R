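# Independent brute-force oracles, kept deliberately naive: every one
# recomputes its quantity from first principles on tiny instances and
# never calls the package functions it checks.

oraclePearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    num / den
}

oracleTanimoto <- function(a, b) {
    onA <- which(a == 1); onB <- which(b == 1)
    u <- union(onA, onB)
    if (!length(u)) return(0)
    length(intersect(onA, onB)) / length(u)
}

oracleDice <- function(a, b) {
    onA <- which(a == 1); onB <- which(b == 1)
    if (!length(onA) && !length(onB)) return(0)
    2 * length(intersect(onA, onB)) / (length(onA) + length(onB))
}

oracleIdf <- function(bits) {
    # bits: compounds x motifs 0/1; returns weighted matrix
    out <- bits * 0
    for (j in seq_len(ncol(bits))) {
        cj <- sum(bits[, j])
        if (cj == 0) next
        w <- log(nrow(bits) / cj)
        for (i in seq_len(nrow(bits)))
            if (bits[i, j] == 1) out[i, j] <- w
    }
    out
}

# Max log risk ratio over single motifs and unordered motif pairs
# present in >= 1 member of ci (rows of bits), optionally restricted to
# the query compound's motifs.
oracleMaxRr <- function(bits, ci, query = NULL) {
    cand <- colnames(bits)
    if (!is.null(query)) cand <- cand[bits[query, ] == 1]
    best <- -Inf
    for (m in cand) {
        pSet <- mean(bits[ci, m])
        if (pSet == 0) next
        best <- max(best, log(pSet / mean(bits[, m])))
    }
    if (length(cand) >= 2) {
        combs <- combn(cand, 2)
        for (k in seq_len(ncol(combs))) {
            mm <- combs[, k]
            both <- bits[, mm[1]] * bits[, mm[2]]
            pSet <- mean(both[rownames(bits) %in% ci])
            if (pSet == 0) next
            best <- max(best, log(pSet / mean(both)))
        }
    }
    best
}

# Enumerated PR points: one per distinct threshold, predicted = score
# >= t, missing scores never predicted.
oraclePrPoints <- function(score, label) {
    thr <- sort(unique(score[!is.na(score)]), decreasing = TRUE)
    do.call(rbind, lapply(thr, function(t) {
        pred <- !is.na(score) & score >= t
        tp <- sum(pred & label); fp <- sum(pred & !label)
        fn <- sum(label) - tp
        data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
                   precision = tp / (tp + fp), recall = tp / sum(label))
    }))
}

oracleAucPc <- function(recall, precision) {
    keep <- recall > 0
    recall <- recall[keep]; precision <- precision[keep]
    best <- tapply(precision, recall, max)
    r <- as.numeric(names(best)); p <- as.numeric(best)
    o <- order(r); r <- r[o]; p <- p[o]
    area <- r[1] * p[1]
    if (length(r) > 1)
        for (i in 2:length(r))
            area <- area + (r[i] - r[i - 1]) * (p[i] + p[i - 1]) / 2
    area
}

oracleWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    (mean(a) - mean(b)) / sqrt(va + vb)
}
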