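# Small in-code fixtures shared across test files.

makeDataset <- function(fd, pval = NULL, compounds = NULL,
                        zygosity = "heterozygous") {
    fd <- as.matrix(fd)
    if (is.null(rownames(fd))) rownames(fd) <- paste0("g", seq_len(nrow(fd)))
    if (is.null(colnames(fd))) colnames(fd) <- paste0("c", seq_len(ncol(fd)))
    if (is.null(pval)) {
        pval <- matrix(0.5, nrow(fd), ncol(fd), dimnames = dimnames(fd))
        pval[is.na(fd)] <- NA
    }
    if (is.null(compounds)) compounds <- colnames(fd)
    cond <- data.frame(condition_id = colnames(fd), compound_id = compounds)
    FitnessDataset(fd, pval, cond, zygosity)
}

makeFingerprints <- function(bitList, nMotifs = 8) {
    # bitList: named list of motif index vectors
    bits <- matrix(0, length(bitList), nMotifs,
                   dimnames = list(names(bitList),
                                   paste0("m", seq_len(nMotifs) + 326L)))
    for (cp in names(bitList)) bits[cp, bitList[[cp]]] <- 1
    FingerprintMatrix(bits)
}

makeCallsMatrix <- function(sensitive, genes, compounds) {
    # sensitive: named list gene -> compound ids with significant calls
    calls <- matrix(FALSE, length(genes), length(compounds),
                    dimnames = list(genes, compounds))
    for (g in names(sensitive)) calls[g, sensitive[[g]]] <- TRUE
    calls
}

smallSimulation <- function(seed = 11L) {
    cfg <- syntheticConfig(nGenes = 120L, nCompounds = 24L,
                           nComplexes = 12L, nFamilies = 6L,
                           nMdrGenes = 5L)
    simulateChemogenomics(cfg, seed = seed)
}
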