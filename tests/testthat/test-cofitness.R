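test_that("Pearson co-fitness matches hand values and the brute-force oracle", {
    fd <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                c = c(4, 3, 2, 1), d = c(1, 3, 2, 4))
    ds <- makeDataset(fd)
    cm <- cofitnessMatrix(ds, "pearson", "log2ratio", minOverlap = 4)
    S <- scores(cm)
    expect_equal(S["a", "b"], 1.0)
    expect_equal(S["a", "c"], -1.0)
    expect_equal(S["a", "d"], 0.8)

    set.seed(31)
    for (i in 1:20) {
        x <- rnorm(6); y <- rnorm(6)
        dsr <- makeDataset(rbind(p = x, q = y))
        Sr <- scores(cofitnessMatrix(dsr, "pearson", minOverlap = 6))
        expect_equal(Sr["p", "q"], oraclePearson(x, y))
    }
})

test_that("the significance threshold is mean plus three sample SDs of pair scores", {
    mk <- function(vals) {
        S <- diag(3) * 0 + 1
        S[upper.tri(S)] <- vals
        S[lower.tri(S)] <- t(S)[lower.tri(S)]
        dimnames(S) <- list(letters[1:3], letters[1:3])
        new("CofitnessMatrix", scores = S, metric = "pearson",
            scoreType = "log2ratio", minOverlap = 1)
    }
    expect_equal(cofitnessThreshold(mk(c(-0.1, 0, 0.1))), 0.3)
    expect_equal(cofitnessThreshold(mk(c(0.2, 0.2, 0.2))), 0.2)
})

test_that("pairs below the overlap floor are reported missing", {
    fd <- rbind(a = c(1, 2, 3, NA, NA), b = c(2, 1, NA, 4, 5),
                c = c(1, 2, 3, 4, 5))
    ds <- makeDataset(fd)
    S <- scores(cofitnessMatrix(ds, "pearson", minOverlap = 3))
    expect_true(is.na(S["a", "b"]))   # overlap 2 < 3
    expect_false(is.na(S["a", "c"])) # overlap 3
})

test_that("Pearson is affine-invariant and Spearman monotone-invariant per gene", {
    set.seed(5)
    fd <- matrix(rnorm(50), 5, 10)
    rownames(fd) <- paste0("g", 1:5)
    ds <- makeDataset(fd)
    fd2 <- fd
    fd2["g1", ] <- 3 * fd["g1", ] + 7          # positive affine
    fd3 <- fd
    fd3["g2", ] <- exp(fd["g2", ])             # monotone
    p1 <- scores(cofitnessMatrix(ds, "pearson"))
    p2 <- scores(cofitnessMatrix(makeDataset(fd2), "pearson"))
    expect_equal(p1["g1", "g3"], p2["g1", "g3"])
    s1 <- scores(cofitnessMatrix(ds, "spearman"))
    s3 <- scores(cofitnessMatrix(makeDataset(fd3), "spearman"))
    expect_equal(s1["g2", "g4"], s3["g2", "g4"])
    # symmetry holds for all metrics
    for (m in c("pearson", "spearman", "euclidean", "binary_cosine")) {
        S <- scores(cofitnessMatrix(ds, m))
        expect_equal(S, t(S))
    }
})

test_that("paralog pairs with elevated co-fitness are detected; Welch statistic matches the formula", {
    S <- matrix(0, 10, 10,
                dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
    set.seed(9)
    S[upper.tri(S)] <- rnorm(45, 0, 0.02)
    parPairs <- rbind(c("g1", "g2"), c("g3", "g4"),
                      c("g5", "g6"), c("g7", "g8"))
    parScores <- c(0.9, 0.88, 0.92, 0.9)
    S[parPairs] <- parScores
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    diag(S) <- 1
    cm <- new("CofitnessMatrix", scores = S, metric = "pearson",
              scoreType = "log2ratio", minOverlap = 1)
    ann <- data.frame(gene_id = paste0("g", 1:10),
                      essential = FALSE, hom_rich_medium_fd = 0,
                      paralog_partner = c("g2", "g1", "g4", "g3", "g6",
                                          "g5", "g8", "g7", NA, NA),
                      processes = "P01")
    res <- paralogCofitnessTest(cm, ann)
    expect_lt(res$p.value, 0.01)
    expect_gt(res$statistic, 0)
    expect_gt(res$meanParalog, res$meanBackground)
    # Welch statistic agrees with the hand formula on the same groups
    bg <- S[upper.tri(S)]
    bg <- bg[!bg %in% parScores]
    expect_equal(res$statistic, oracleWelch(parScores, bg))
})

test_that("essential-partner fractions count partners above threshold", {
    S <- matrix(-1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
    diag(S) <- 1
    # g1's partners above 0.5: g2, g3, g4
    S["g1", c("g2", "g3", "g4")] <- S[c("g2", "g3", "g4"), "g1"] <- 0.9
    cm <- new("CofitnessMatrix", scores = S, metric = "pearson",
              scoreType = "log2ratio", minOverlap = 1)
    ann <- data.frame(gene_id = paste0("g", 1:4),
                      essential = c(FALSE, TRUE, TRUE, FALSE),
                      hom_rich_medium_fd = 0,
                      paralog_partner = NA_character_, processes = "P01")
    res <- essentialPartnerFractions(cm, ann, threshold = 0.5)
    pg <- res$perGene
    expect_equal(pg$fraction_essential[pg$gene_id == "g1"], 2 / 3)
    # a gene with zero partners is missing and excluded from the summary
    S2 <- S; S2["g1", ] <- S2[, "g1"] <- -1; diag(S2) <- 1
    cm2 <- new("CofitnessMatrix", scores = S2, metric = "pearson",
               scoreType = "log2ratio", minOverlap = 1)
    res2 <- essentialPartnerFractions(cm2, ann, threshold = 0.5)
    expect_true(all(is.na(res2$perGene$fraction_essential)))
})

test_that("co-complex pairs show enriched co-fitness when a module responds", {
    # direct counting case: one complex {a, b} with score 0.9
    S <- matrix(0, 4, 4, dimnames = list(c("a", "b", "x", "y"),
                                         c("a", "b", "x", "y")))
    S["a", "b"] <- S["b", "a"] <- 0.9
    diag(S) <- 1
    cm <- new("CofitnessMatrix", scores = S, metric = "pearson",
              scoreType = "log2ratio", minOverlap = 1)
    res <- cocomplexEnrichment(cm, list(cplx1 = c("a", "b")))
    expect_equal(res$meanWithin, 0.9)
    expect_equal(res$meanBackground, 0)

    # planted-truth recovery on the generator with module signal
    cfg <- syntheticConfig(nGenes = 250L, nCompounds = 50L,
                           nComplexes = 20L, nMdrGenes = 8L)
    sim <- simulateChemogenomics(cfg, seed = 3L)
    cmHom <- cofitnessMatrix(sim$hom, "pearson", "log2ratio")
    resp <- unname(sim$truth$moduleOfFamily)
    enr <- cocomplexEnrichment(cmHom, sim$complexes[resp])
    expect_gt(enr$meanWithin, enr$meanBackground)
    expect_lt(enr$p.value, 0.01)
})

test_that("the paralog test is calibrated under the null", {
    set.seed(404)
    reject <- vapply(seq_len(200), function(i) {
        n <- 12L
        genes <- paste0("g", seq_len(n))
        S <- matrix(0, n, n, dimnames = list(genes, genes))
        S[upper.tri(S)] <- rnorm(n * (n - 1) / 2)
        S[lower.tri(S)] <- t(S)[lower.tri(S)]
        diag(S) <- 1
        cm <- new("CofitnessMatrix", scores = S, metric = "pearson",
                  scoreType = "log2ratio", minOverlap = 1)
        partner <- rep(NA_character_, n)
        partner[1:6] <- genes[c(2, 1, 4, 3, 6, 5)]
        ann <- data.frame(gene_id = genes, essential = FALSE,
                          hom_rich_medium_fd = 0,
                          paralog_partner = partner, processes = "P01")
        paralogCofitnessTest(cm, ann)$p.value < 0.05
    }, TRUE)
    expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("essential query genes have more essential co-fit partners when essentials co-cluster", {
    # essential genes co-cluster: e-block pairs co-fit among themselves,
    # n-block genes co-fit with a mix of essential and non-essential genes
    genes <- c(paste0("e", 1:5), paste0("n", 1:5))
    S <- matrix(0, 10, 10, dimnames = list(genes, genes))
    S[1:5, 1:5] <- 0.9                      # essential module
    S[6:10, 6:10] <- 0.9                    # non-essential module
    S["n1", "e1"] <- S["e1", "n1"] <- 0.9   # one cross link
    diag(S) <- 1
    cm <- new("CofitnessMatrix", scores = S, metric = "pearson",
              scoreType = "log2ratio", minOverlap = 1)
    ann <- data.frame(gene_id = genes,
                      essential = rep(c(TRUE, FALSE), each = 5),
                      hom_rich_medium_fd = 0,
                      paralog_partner = NA_character_, processes = "P01")
    res <- essentialPartnerFractions(cm, ann, threshold = 0.5)
    expect_gt(res$meanEssential, res$meanNonEssential)
    expect_gt(res$meanEssential, 0.9)       # e-queries: mostly essential partners
    expect_lt(res$meanNonEssential, 0.1)
})
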