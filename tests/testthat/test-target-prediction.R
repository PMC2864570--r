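test_that("struct_count is the maximum number of co-sensitive compounds sharing a motif", {
    # four co-sensitive compounds all share motif 1: k = 3 for the query
    fp <- makeFingerprints(list(q = c(1, 4), a = c(1, 2), b = c(1, 3),
                                c = 1, lone = 8))
    calls <- makeCallsMatrix(list(g1 = c("q", "a", "b", "c"),
                                  g2 = "q"),
                             genes = c("g1", "g2"),
                             compounds = c("q", "a", "b", "c", "lone"))
    expect_equal(structCount("g1", "q", calls, fp), 3L)
    # C_i = {query} alone
    expect_equal(structCount("g2", "q", calls, fp), 0L)
    # max over motifs: motif A shared by {q, a}, motif B by {q, a, b}
    fp2 <- makeFingerprints(list(q = c(1, 2), a = c(1, 2), b = 2))
    calls2 <- makeCallsMatrix(list(g = c("q", "a", "b")),
                              genes = "g", compounds = c("q", "a", "b"))
    expect_equal(structCount("g", "q", calls2, fp2), 2L)
})

test_that("risk-ratio enrichment evaluates ln(P(m|Ci)/P(m)) over motifs and pairs", {
    # P(m|Ci) = 0.75 over 4 sensitizing compounds, P(m) = 4/80 = 0.05
    nC <- 80L
    ids <- sprintf("c%02d", seq_len(nC))
    bits <- matrix(0, nC, 5, dimnames = list(ids, paste0("m", 1:5)))
    bits[ids[1:3], "m1"] <- 1     # 3 carriers inside C_i
    bits[ids[5], "m1"] <- 1       # 1 outside
    bits[, "m3"] <- 1             # ubiquitous: P(m|Ci) = P(m) -> RR 0
    bits[ids[30:40], "m5"] <- 1   # present only outside C_i
    fp <- FingerprintMatrix(bits)
    ci <- ids[1:4]
    calls <- makeCallsMatrix(list(g = ci), genes = "g", compounds = ids)
    res <- structEnrichment("g", calls, fp, queryCompound = ids[1])
    expect_equal(res$rr, log(15))
    expect_equal(res$pInSet, 0.75)
    expect_equal(res$pGlobal, 0.05)
    expect_identical(res$motifs, "m1")
    expect_false(res$flag)
    # the ubiquitous motif alone gives RR = ln(1) = 0
    callsU <- makeCallsMatrix(list(g2 = ids[10:12]), genes = "g2",
                              compounds = ids)
    bitsU <- bits * 0; bitsU[, "m3"] <- 1
    resU <- structEnrichment("g2", callsU, FingerprintMatrix(bitsU),
                             ids[10])
    expect_equal(resU$rr, 0)
    # a motif absent from all of C_i is never selected (gene-centric mode)
    res2 <- structEnrichment("g", calls, fp, ids[1], pairSpecific = FALSE)
    expect_false("m5" %in% res2$motifs)
    expect_true(is.finite(res2$rr))
    # empty C_i returns the flagged sentinel
    calls0 <- makeCallsMatrix(list(), genes = "g", compounds = ids)
    res0 <- structEnrichment("g", calls0, fp, ids[1])
    expect_equal(res0$rr, 0)
    expect_true(res0$flag)
})

test_that("risk-ratio enrichment matches the brute-force oracle on small instances", {
    set.seed(23)
    for (i in 1:15) {
        n <- 6L
        ids <- paste0("c", 1:n)
        bits <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                       dimnames = list(ids, paste0("m", 1:4)))
        bits[1, ] <- pmax(bits[1, ], c(1, 0, 0, 0)) # query carries m1
        ci <- ids[1:3]
        calls <- makeCallsMatrix(list(g = ci), genes = "g", compounds = ids)
        res <- structEnrichment("g", calls, FingerprintMatrix(bits), ids[1])
        expect_equal(res$rr, oracleMaxRr(bits, ci, query = ids[1]))
    }
})

test_that("mean structural similarity over C_i handles pairs and singletons", {
    fp <- makeFingerprints(list(a = c(1, 2), b = c(1, 2)))
    calls <- makeCallsMatrix(list(g = c("a", "b")), "g", c("a", "b"))
    expect_equal(structSimilarityMean("g", calls, fp)$value, 1.0)
    # pairwise Tanimotos {1/3, 1/3, 1} -> mean 5/9
    fp2 <- makeFingerprints(list(a = c(1, 2), b = c(1, 2), c = c(1, 3)))
    calls2 <- makeCallsMatrix(list(g = c("a", "b", "c")), "g",
                              c("a", "b", "c"))
    expect_equal(structSimilarityMean("g", calls2, fp2)$value, 5 / 9)
    calls1 <- makeCallsMatrix(list(g = "a"), "g", c("a", "b"))
    res1 <- structSimilarityMean("g", calls1, fp)
    expect_equal(res1$value, 0)
    expect_true(res1$flag)
})

test_that("secondary-ligand slots follow co-inhibition ranking with zero padding", {
    comps <- c("q", "s1", "s2", "s3")
    S <- diag(1, 4); dimnames(S) <- list(comps, comps)
    S["q", c("s1", "s2", "s3")] <- S[c("s1", "s2", "s3"), "q"] <-
        c(0.9, 0.8, 0.7)
    cm <- new("CoinhibitionMatrix", scores = S, zygosity = "heterozygous",
              minOverlap = 1)
    fd <- matrix(c(0, 6, 4, 2), 1, dimnames = list("g", comps))
    ds <- makeDataset(fd, compounds = comps)
    out <- secondaryLigandFeatures("q", "g", cm, ds)
    expect_equal(unname(out[1:3]), c(6, 4, 2))
    expect_equal(unname(out[4:10]), rep(0, 7))
    expect_equal(unname(out["secondary_mean"]), 12 / 10)
    expect_equal(unname(out["secondary_median"]), 0)
    # all ten secondary fds equal 1 -> mean 1, median 1
    comps10 <- c("q", paste0("s", 1:10))
    S10 <- diag(1, 11); dimnames(S10) <- list(comps10, comps10)
    S10["q", -1] <- S10[-1, "q"] <- seq(0.9, 0.4, length.out = 10)
    cm10 <- new("CoinhibitionMatrix", scores = S10,
                zygosity = "heterozygous", minOverlap = 1)
    fd10 <- matrix(c(0, rep(1, 10)), 1, dimnames = list("g", comps10))
    ds10 <- makeDataset(fd10, compounds = comps10)
    out10 <- secondaryLigandFeatures("q", "g", cm10, ds10)
    expect_equal(unname(out10["secondary_mean"]), 1)
    expect_equal(unname(out10["secondary_median"]), 1)
    # a missing fitness defect fills its slot with 0
    fdNa <- fd; fdNa[1, "s1"] <- NA
    outNa <- secondaryLigandFeatures("q", "g", cm, makeDataset(fdNa,
        compounds = comps))
    expect_equal(unname(outNa[1]), 0)
})

test_that("the feature table always has the 20 named features with coherent summaries", {
    sim <- smallSimulation(seed = 10L)
    hetC <- collapseReplicates(sim$het)
    calls <- significantCalls(hetC)
    cm <- coinhibitionMatrix(hetC)
    pos <- generateKnownInteractions(sim$truth, 12L, seed = 2L)
    tr <- assembleTrainingSet(pos, "balanced", seed = 4L)
    ft <- buildFeatureTable(tr, hetC, sim$annotations, calls,
                            sim$fingerprints, cm)
    expect_identical(sum(colnames(ft) %in% featureNames()), 20L)
    expect_identical(length(featureNames()), 20L)
    slots <- as.matrix(ft[, paste0("secondary_ligands_", 1:10)])
    expect_equal(rowMeans(slots), ft$secondary_mean)
    expect_equal(apply(slots, 1, median), ft$secondary_median)
    # a pair with missing het fd gets the documented sentinels
    fd <- fdScores(hetC)
    g <- rownames(fd)[1]; cp <- colnames(fd)[1]
    fd2 <- fd; fd2[g, cp] <- NA
    pv2 <- pValues(hetC); pv2[g, cp] <- NA
    ds2 <- FitnessDataset(fd2, pv2,
                          as.data.frame(SummarizedExperiment::colData(hetC)),
                          "heterozygous")
    ft2 <- buildFeatureTable(data.frame(gene_id = g, compound_id = cp),
                             ds2, sim$annotations, calls,
                             sim$fingerprints, cm)
    expect_equal(ft2$ratio, 0)
    expect_equal(ft2$pvalue, 1)
    expect_true(attr(ft2, "flags")$missing_fd)
})

test_that("balanced negatives preserve degrees and avoid positives; unbalanced takes the complement", {
    pos <- data.frame(compound_id = paste0("c", 1:4),
                      gene_id = paste0("g", 1:4), label = "positive",
                      source = "curated")
    tr <- assembleTrainingSet(pos, "balanced", seed = 6L)
    neg <- tr[tr$label == "negative", ]
    expect_equal(nrow(neg), 4L)
    expect_equal(sort(neg$compound_id), sort(pos$compound_id))
    expect_equal(sort(neg$gene_id), sort(pos$gene_id))
    expect_false(any(paste(neg$compound_id, neg$gene_id) %in%
                     paste(pos$compound_id, pos$gene_id)))
    # a perfect matching's negatives are a disjoint perfect matching
    expect_false(anyDuplicated(neg$gene_id) > 0)

    pos5 <- data.frame(compound_id = paste0("c", 1:5),
                       gene_id = paste0("g", 1:5), label = "positive",
                       source = "curated")
    un <- assembleTrainingSet(pos5, "unbalanced")
    expect_equal(sum(un$label == "negative"), 20L)  # 25 - 5

    # infeasible: single compound, single gene, one positive
    pos1 <- data.frame(compound_id = "c1", gene_id = "g1",
                       label = "positive", source = "curated")
    expect_error(assembleTrainingSet(pos1, "balanced", maxSwaps = 10L,
                                     maxRestarts = 2L),
                 "degree")
})

test_that("the stump minimizes training error and the forest votes in tenths", {
    set.seed(77)
    tab <- data.frame(gene_id = "g", compound_id = paste0("c", 1:40),
                      ratio = c(rnorm(20, 5), rnorm(20, 0)),
                      pvalue = runif(40),
                      label = rep(c("positive", "negative"), each = 20))
    stump <- trainClassifier(tab, "stump",
                             features = c("ratio", "pvalue"))
    expect_identical(stump@feature, "ratio")
    expect_identical(predict(stump, tab, type = "decision"),
                     tab$label == "positive")
    forest <- trainClassifier(tab, "random_forest",
                              features = c("ratio", "pvalue"), seed = 5L)
    conf <- predict(forest, tab, type = "confidence")
    expect_true(all(abs(conf * 10 - round(conf * 10)) < 1e-9))
    expect_true(all(conf >= 0 & conf <= 1))
    # floor(sqrt(M)) + 1 candidate features per node
    expect_identical(forest@mtry, 2L)
    expect_error(trainClassifier(tab[1:20, ], "stump",
                                 features = c("ratio", "pvalue")),
                 "both classes")
})

test_that("forest models survive a JSON round trip", {
    set.seed(42)
    tab <- data.frame(gene_id = "g", compound_id = paste0("c", 1:30),
                      ratio = c(rnorm(15, 3), rnorm(15)),
                      genefreq = rpois(30, 4),
                      label = rep(c("positive", "negative"), each = 15))
    forest <- trainClassifier(tab, "random_forest",
                              features = c("ratio", "genefreq"), seed = 2L)
    path <- file.path(withr::local_tempdir(), "model.json")
    writeModelJson(forest, path)
    back <- readModelJson(path)
    expect_equal(predict(back, tab, type = "confidence"),
                 predict(forest, tab, type = "confidence"))
    stump <- trainClassifier(tab, "stump", features = c("ratio", "genefreq"))
    writeModelJson(stump, path)
    backS <- readModelJson(path)
    expect_equal(predict(backS, tab, type = "decision"),
                 predict(stump, tab, type = "decision"))
})

test_that("cross-validation recovers planted targets and the stump picks the fitness defect", {
    sim <- smallSimulation(seed = 20L)
    hetC <- collapseReplicates(sim$het)
    calls <- significantCalls(hetC)
    cm <- coinhibitionMatrix(hetC)
    pos <- generateKnownInteractions(sim$truth, nrow(sim$truth$planted),
                                     seed = 3L)
    tr <- assembleTrainingSet(pos, "balanced", seed = 3L)
    ft <- buildFeatureTable(tr, hetC, sim$annotations, calls,
                            sim$fingerprints, cm)
    cv <- crossValidate(ft, "random_forest", k = 4L, seed = 3L)
    expect_gte(cv$auc, 0.85)
    stump <- trainClassifier(ft, "stump")
    expect_identical(stump@feature, "ratio")
    expect_error(crossValidate(ft, "stump", k = 1000L), "smaller class")
    # the hand-rolled forest agrees with an independent implementation
    # on strongly separable data
    rf <- randomForest::randomForest(
        x = ft[, featureNames()], y = factor(ft$label), ntree = 50)
    ext <- predict(rf, ft[, featureNames()], type = "prob")[, "positive"]
    ours <- predict(trainClassifier(ft, "random_forest", seed = 4L), ft,
                    type = "confidence")
    expect_gt(cor(ext, ours, method = "spearman"), 0.7)
})

test_that("random labels give precision near the class fraction at every threshold", {
    set.seed(55)
    n <- 200L
    tab <- data.frame(gene_id = "g", compound_id = paste0("c", 1:n),
                      ratio = rnorm(n), pvalue = runif(n),
                      label = sample(c("positive", "negative"), n,
                                     replace = TRUE, prob = c(0.3, 0.7)))
    cv <- crossValidate(tab, "stump", k = 5L, seed = 9L,
                        features = c("ratio", "pvalue"))
    pts <- prPoints(cv$curve)
    broad <- pts[pts$tp + pts$fp >= 50, ]
    expect_true(all(abs(broad$precision - mean(tab$label == "positive"))
                    < 0.2))
})

test_that("top-prediction filtering applies all five criteria", {
    genes <- paste0("g", 1:12)
    comps <- paste0("c", 1:12)
    fd <- matrix(0.1, 12, 12, dimnames = list(genes, comps))
    diag(fd) <- 6                      # reciprocal top hits, high fd
    fd["g2", "c2"] <- 5.0              # inclusive boundary case
    fd["g3", "c3"] <- 4.0              # below the fd cutoff
    ds <- makeDataset(fd, compounds = comps)
    ann <- data.frame(gene_id = genes,
                      essential = c(TRUE, TRUE, TRUE, FALSE,
                                    rep(TRUE, 8)),
                      hom_rich_medium_fd = c(rep(NA, 3), 0.1, rep(NA, 8)),
                      paralog_partner = NA_character_, processes = "P01")
    preds <- data.frame(gene_id = genes, compound_id = comps,
                        confidence = c(0.9, 0.9, 0.9, 0.9, 0.69,
                                       rep(0.8, 7)))
    out <- filterTopPredictions(preds, ds, ann)
    expect_true(all(c("g1", "g2") %in% out$gene_id))   # fd 6 and fd 5.0 pass
    expect_false("g3" %in% out$gene_id)                # fd 4 < 5
    expect_false("g4" %in% out$gene_id)                # no phenotype
    expect_false("g5" %in% out$gene_id)                # confidence 0.69 < 0.7
})

test_that("OD calibration applies the printed affine map", {
    expect_equal(calibrateOD(0), -1.0543)
    expect_equal(calibrateOD(1), 11.2173)
    x <- c(0.2, 0.5, 1.3)
    expect_equal(calibrateOD(2 * x) - calibrateOD(x), 12.2716 * x)
    expect_error(calibrateOD(-0.1), "non-negative")
})
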