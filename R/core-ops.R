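#' @describeIn collapseReplicates Several screening conditions often
#'   probe the same compound (replicates, concentrations, timepoints).
#'   Each (gene, compound) group is collapsed to the maximum non-missing
#'   fitness defect (greatest sensitivity); the retained P-value is the
#'   one paired with the selected score, so each collapsed cell is a
#'   coherent (fd, p) record. All-missing groups stay missing. The
#'   result has one column per compound and is idempotent under further
#'   collapsing.
#' @return a \linkS4class{FitnessDataset} with one column per compound.
#' @export
setMethod("collapseReplicates", "FitnessDataset", function(ds) {
    fd <- fdScores(ds)
    pv <- pValues(ds)
    comp <- compoundIds(ds)
    compounds <- unique(comp)
    nOut <- length(compounds)
    outFd <- matrix(NA_real_, nrow(fd), nOut,
                    dimnames = list(rownames(fd), compounds))
    outPv <- outFd
    for (k in seq_len(nOut)) {
        cols <- which(comp == compounds[k])
        sub <- fd[, cols, drop = FALSE]
        subp <- pv[, cols, drop = FALSE]
        hasAny <- rowSums(!is.na(sub)) > 0L
        if (!any(hasAny)) next
        pick <- max.col(replace(sub, is.na(sub), -Inf), ties.method = "first")
        idx <- cbind(seq_len(nrow(sub)), pick)
        outFd[hasAny, k] <- sub[idx][hasAny]
        outPv[hasAny, k] <- subp[idx][hasAny]
    }
    conditions <- data.frame(condition_id = compounds,
                             compound_id = compounds,
                             concentration = "collapsed",
                             timepoint = "collapsed")
    FitnessDataset(outFd, outPv, conditions, zygosity(ds))
})

#' Call significant sensitivities
#'
#' An entry is a significant call when its P-value falls strictly below
#' the cutoff (P < 0.01 by default) and the fitness-defect score is
#' observed. Missing entries are never called.
#'
#' @param ds a \linkS4class{FitnessDataset}.
#' @param pCutoff significance cutoff in (0, 1); the comparison is
#'   strict.
#' @return logical gene-by-condition matrix (no missing values).
#' @examples
#' # a P-value of exactly the cutoff is not called
#' @export
significantCalls <- function(ds, pCutoff = 0.01) {
    stopifnot(is.numeric(pCutoff), length(pCutoff) == 1L)
    if (is.na(pCutoff) || pCutoff <= 0 || pCutoff >= 1)
        stop("pCutoff must lie strictly between 0 and 1")
    calls <- pValues(ds) < pCutoff & !is.na(fdScores(ds))
    calls[is.na(calls)] <- FALSE
    calls
}

#' Per-gene and per-compound sensitivity frequencies
#'
#' Marginal counts of significant calls from a replicate-collapsed
#' dataset: \code{genefreq} is the number of compounds causing
#' sensitivity in each gene, \code{drugfreq} the number of deletion
#' strains sensitive to each compound. Both marginals sum to the total
#' number of calls.
#'
#' @param calls logical matrix from [significantCalls()], with
#'   compound-level columns.
#' @return list with numeric vectors \code{genefreq} and
#'   \code{drugfreq}.
#' @export
sensitivityFrequencies <- function(calls) {
    list(genefreq = rowSums(calls), drugfreq = colSums(calls))
}
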