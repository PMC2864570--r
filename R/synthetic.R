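#' Configuration for the synthetic chemogenomic generator
#'
#' The generator plants the structure the downstream analyses exploit:
#' compound families with shared substructure cores and ATC classes,
#' protein complexes that respond as modules in the homozygous assay,
#' per-compound target genes that sensitize heterozygous strains, and
#' promiscuous multi-drug-resistance (MDR) genes. Defaults emulate the
#' shape and signal structure of genome-wide pooled deletion screens at
#' desk scale (600 genes, 80 compounds, two conditions per compound).
#'
#' Effect sizes are on the log2-ratio fitness-defect scale:
#' \code{deltaTarget} is added to a heterozygous target strain in its
#' compound's conditions, \code{deltaModule} to homozygous strains of a
#' responding module, and \code{deltaMdr} to MDR strains in the
#' conditions of the compounds they respond to. Noise is i.i.d.
#' Gaussian with standard deviation \code{noiseSd}.
#'
#' @param nGenes,nCompounds,conditionsPerCompound dataset shape.
#' @param fractionEssential fraction of genes flagged essential
#'   (assigned complex-wise so essential genes co-cluster).
#' @param nComplexes,complexSizeRange disjoint protein complexes and
#'   their size range.
#' @param nProcesses number of biological-process labels (32, matching
#'   a GO Slim-sized label set).
#' @param nFamilies number of compound families; each family shares a
#'   substructure core, an ATC level-3 class and a planted target.
#' @param fingerprintLength fingerprint width (554 PubChem-style keys).
#' @param familyCoreMotifs core motifs per family.
#' @param backgroundBitRate probability of a background fingerprint bit.
#' @param deltaTarget,deltaModule,deltaMdr planted effect sizes.
#' @param nMdrGenes,mdrCompoundFraction MDR gene count and the fraction
#'   of compounds each MDR gene responds to.
#' @param noiseSd Gaussian noise SD on the log2-ratio scale.
#' @param missingRate fraction of entries masked missing.
#' @param paralogFraction fraction of genes given a within-module
#'   paralog partner.
#' @param processPairFraction fraction of within-process gene pairs
#'   added to the reference network beyond within-complex pairs.
#' @return a validated config (list with class
#'   \code{"chemofit_config"}).
#' @export
syntheticConfig <- function(nGenes = 600L, nCompounds = 80L,
                            conditionsPerCompound = 2L,
                            fractionEssential = 0.2,
                            nComplexes = 40L, complexSizeRange = c(2L, 12L),
                            nProcesses = 32L, nFamilies = 10L,
                            fingerprintLength = 554L, familyCoreMotifs = 6L,
                            backgroundBitRate = 0.03,
                            deltaTarget = 4.0, deltaModule = 2.5,
                            nMdrGenes = 15L, deltaMdr = 2.0,
                            mdrCompoundFraction = 0.6,
                            noiseSd = 0.8, missingRate = 0.02,
                            paralogFraction = 0.1,
                            processPairFraction = 0.02) {
    cfg <- list(nGenes = as.integer(nGenes),
                nCompounds = as.integer(nCompounds),
                conditionsPerCompound = as.integer(conditionsPerCompound),
                fractionEssential = fractionEssential,
                nComplexes = as.integer(nComplexes),
                complexSizeRange = as.integer(complexSizeRange),
                nProcesses = as.integer(nProcesses),
                nFamilies = as.integer(nFamilies),
                fingerprintLength = as.integer(fingerprintLength),
                familyCoreMotifs = as.integer(familyCoreMotifs),
                backgroundBitRate = backgroundBitRate,
                deltaTarget = deltaTarget, deltaModule = deltaModule,
                nMdrGenes = as.integer(nMdrGenes), deltaMdr = deltaMdr,
                mdrCompoundFraction = mdrCompoundFraction,
                noiseSd = noiseSd, missingRate = missingRate,
                paralogFraction = paralogFraction,
                processPairFraction = processPairFraction)
    counts <- c("nGenes", "nCompounds", "conditionsPerCompound",
                "nProcesses", "fingerprintLength", "familyCoreMotifs")
    for (f in counts)
        if (cfg[[f]] <= 0L) stop(f, " must be positive")
    probs <- c("fractionEssential", "backgroundBitRate", "missingRate",
               "mdrCompoundFraction", "paralogFraction",
               "processPairFraction")
    for (f in probs)
        if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
    if (cfg$noiseSd <= 0) stop("noiseSd must be positive")
    if (cfg$nFamilies > cfg$nCompounds)
        stop("family count exceeds compound count")
    if (cfg$nFamilies * cfg$familyCoreMotifs > cfg$fingerprintLength)
        stop("family core motifs exceed the fingerprint length")
    structure(cfg, class = "chemofit_config")
}

.padId <- function(prefix, i, n) {
    sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

#' Generate a synthetic compound library
#'
#' Compounds are partitioned into families. Each family owns a disjoint
#' set of core substructure motifs switched on in all its members;
#' background bits elsewhere are on independently with a low
#' probability. All compounds of a family share one ATC level-3 prefix
#' (first four characters); the last three characters vary per
#' compound. Deterministic given the seed.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer RNG seed.
#' @return list with \code{compounds} (annotation data.frame),
#'   \code{fingerprints} (\linkS4class{FingerprintMatrix}),
#'   \code{family} (named compound-to-family vector),
#'   \code{familyCores} (list of core motif columns per family) and
#'   \code{familyAtc} (named level-3 prefix per family).
#' @export
generateCompoundLibrary <- function(config, seed) {
    withr::with_seed(seed, {
        nC <- config$nCompounds
        nF <- config$nFamilies
        compounds <- .padId("cpd", seq_len(nC), nC)
        famIds <- .padId("fam", seq_len(nF), nF)
        family <- stats::setNames(
            famIds[sample(rep(seq_len(nF), length.out = nC))], compounds)
        coreCols <- sample(config$fingerprintLength,
                           nF * config$familyCoreMotifs)
        familyCores <- split(coreCols,
                             rep(famIds, each = config$familyCoreMotifs))
        bits <- matrix(
            as.numeric(stats::runif(nC * config$fingerprintLength) <
                       config$backgroundBitRate),
            nrow = nC,
            dimnames = list(compounds,
                            paste0("m", seq_len(config$fingerprintLength) +
                                        326L)))
        for (cp in compounds)
            bits[cp, familyCores[[family[cp]]]] <- 1
        atcL1 <- sample(LETTERS, nF, replace = TRUE)
        prefix <- paste0(atcL1, sprintf("%02d", sample(0:99, nF)),
                         sample(LETTERS, nF, replace = TRUE))
        while (anyDuplicated(prefix))
            prefix[duplicated(prefix)] <- paste0(
                sample(LETTERS, sum(duplicated(prefix)), replace = TRUE),
                sprintf("%02d", sample(0:99, sum(duplicated(prefix)),
                                       replace = TRUE)),
                sample(LETTERS, sum(duplicated(prefix)), replace = TRUE))
        familyAtc <- stats::setNames(prefix, famIds)
        atc <- paste0(familyAtc[family],
                      sample(LETTERS, nC, replace = TRUE),
                      sprintf("%02d", sample(0:99, nC, replace = TRUE)))
        ann <- data.frame(compound_id = compounds,
                          smiles = NA_character_,
                          atc_codes = atc,
                          tested_het = TRUE, tested_hom = TRUE,
                          stringsAsFactors = FALSE)
        list(compounds = ann,
             fingerprints = FingerprintMatrix(bits),
             family = family,
             familyCores = familyCores,
             familyAtc = familyAtc)
    })
}

#' Generate synthetic gene annotations, complexes and reference network
#'
#' Disjoint protein complexes of configured sizes are carved out of the
#' gene list; each complex carries one process label and every complex
#' used downstream has at least two members. The reference functional
#' network contains every within-complex pair plus a random sample of
#' within-process pairs. Essentiality is assigned complex-wise (all
#' members share the flag) so essential genes co-cluster; paralog
#' partners are drawn within complexes. Deterministic given the seed.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer RNG seed.
#' @return list with \code{annotations} (gene data.frame),
#'   \code{complexes} (named member list), \code{referenceNetwork}
#'   (canonical pair data.frame) and \code{geneModule} (named
#'   gene-to-complex vector, NA outside complexes).
#' @export
generateGeneAnnotations <- function(config, seed) {
    withr::with_seed(seed, {
        nG <- config$nGenes
        genes <- .padId("g", seq_len(nG), nG)
        sizes <- sample(seq(config$complexSizeRange[1],
                            config$complexSizeRange[2]),
                        config$nComplexes, replace = TRUE)
        if (sum(sizes) > nG)
            stop("complex sizes exceed gene count")
        shuffled <- sample(genes)
        cplxIds <- .padId("cplx", seq_len(config$nComplexes),
                          config$nComplexes)
        complexes <- stats::setNames(
            split(shuffled[seq_len(sum(sizes))],
                  rep(seq_along(sizes), sizes)), cplxIds)
        geneModule <- stats::setNames(rep(NA_character_, nG), genes)
        for (id in cplxIds) geneModule[complexes[[id]]] <- id

        procIds <- paste0("P", sprintf("%02d", seq_len(config$nProcesses)))
        complexProc <- stats::setNames(
            sample(procIds, config$nComplexes, replace = TRUE), cplxIds)
        proc <- stats::setNames(sample(procIds, nG, replace = TRUE), genes)
        proc[!is.na(geneModule)] <- complexProc[geneModule[!is.na(geneModule)]]
        extra <- stats::runif(nG) < 0.2
        processes <- ifelse(extra,
                            paste(proc, sample(procIds, nG, replace = TRUE),
                                  sep = ";"),
                            proc)

        essential <- stats::setNames(
            stats::runif(nG) < config$fractionEssential, genes)
        for (id in cplxIds)
            essential[complexes[[id]]] <-
                stats::runif(1) < config$fractionEssential

        partner <- stats::setNames(rep(NA_character_, nG), genes)
        targetPairs <- round(config$paralogFraction * nG / 2)
        made <- 0L
        for (id in sample(cplxIds)) {
            if (made >= targetPairs) break
            members <- complexes[[id]]
            free <- members[is.na(partner[members])]
            while (length(free) >= 2L && made < targetPairs) {
                pair <- sample(free, 2L)
                partner[pair[1]] <- pair[2]
                partner[pair[2]] <- pair[1]
                free <- setdiff(free, pair)
                made <- made + 1L
            }
        }

        homFd <- abs(stats::rnorm(nG, 0, 0.2))
        slow <- stats::runif(nG) < 0.25
        homFd[slow] <- stats::runif(sum(slow), 0.5, 3)
        homFd[essential] <- NA_real_
        ann <- data.frame(gene_id = genes,
                          essential = unname(essential),
                          hom_rich_medium_fd = homFd,
                          paralog_partner = unname(partner),
                          processes = processes,
                          stringsAsFactors = FALSE)

        withinComplex <- do.call(rbind, lapply(complexes, function(m)
            if (length(m) >= 2L) t(utils::combn(m, 2L)) else NULL))
        withinComplex <- canonicalPairs(as.data.frame(withinComplex))
        procList <- geneProcesses(ann)
        byProc <- lapply(procIds, function(p)
            names(procList)[vapply(procList, function(x) p %in% x, TRUE)])
        procPairs <- do.call(rbind, lapply(byProc, function(m) {
            if (length(m) < 2L) return(NULL)
            all <- t(utils::combn(m, 2L))
            take <- stats::runif(nrow(all)) < config$processPairFraction
            all[take, , drop = FALSE]
        }))
        network <- withinComplex
        if (!is.null(procPairs) && nrow(procPairs))
            network <- unique(rbind(withinComplex,
                                    canonicalPairs(as.data.frame(procPairs))))
        rownames(network) <- NULL
        list(annotations = ann, complexes = complexes,
             referenceNetwork = network, geneModule = geneModule)
    })
}

#' Generate planted fitness data
#'
#' Builds the heterozygous (HIP) and homozygous (HOP) fitness datasets
#' from the planted truth. Each cell is the sum of the planted effects
#' and i.i.d. Gaussian noise:
#' heterozygous target cells gain \code{deltaTarget}, homozygous cells
#' of a module responding to the condition's compound gain
#' \code{deltaModule}, and MDR strains gain \code{deltaMdr} in the
#' conditions of compounds they respond to (both assays). P-values are
#' the one-sided upper normal tail of fd/noiseSd, so within a column
#' they are monotone decreasing in the fitness defect. A configured
#' fraction of entries (fd and P-value together) is masked missing.
#' Deterministic given the seed.
#'
#' @param config a [syntheticConfig()].
#' @param truth a planted-truth object from [simulateChemogenomics()]
#'   (or assembled with the same fields).
#' @param seed integer RNG seed.
#' @return list with \linkS4class{FitnessDataset}s \code{het} and
#'   \code{hom}.
#' @export
generateFitnessData <- function(config, truth, seed) {
    if (!identical(truth$config[names(config)], unclass(config)))
        stop("truth was generated from a different config")
    withr::with_seed(seed, {
        genes <- truth$genes
        compounds <- truth$compounds
        reps <- config$conditionsPerCompound
        condComp <- rep(compounds, each = reps)
        condIds <- paste0(condComp, "_c", rep(seq_len(reps),
                                              length(compounds)))
        conditions <- data.frame(condition_id = condIds,
                                 compound_id = condComp,
                                 concentration = paste0("conc",
                                     rep(seq_len(reps), length(compounds))),
                                 timepoint = "t1",
                                 stringsAsFactors = FALSE)
        nG <- length(genes); nCond <- length(condIds)

        signalHet <- matrix(0, nG, nCond, dimnames = list(genes, condIds))
        signalHom <- signalHet
        targetOf <- stats::setNames(truth$planted$gene_id,
                                    truth$planted$compound_id)
        for (j in seq_len(nCond)) {
            cp <- condComp[j]
            tg <- targetOf[[cp]]
            if (!is.null(tg) && !is.na(tg))
                signalHet[tg, j] <- signalHet[tg, j] + config$deltaTarget
            fam <- truth$compoundFamily[[cp]]
            mod <- truth$moduleOfFamily[[fam]]
            if (!is.null(mod) && !is.na(mod))
                signalHom[truth$complexes[[mod]], j] <-
                    signalHom[truth$complexes[[mod]], j] + config$deltaModule
        }
        for (g in truth$mdrGenes) {
            cols <- condComp %in% truth$mdrResponse[[g]]
            signalHet[g, cols] <- signalHet[g, cols] + config$deltaMdr
            signalHom[g, cols] <- signalHom[g, cols] + config$deltaMdr
        }

        buildDs <- function(signal, zyg) {
            fd <- signal + matrix(stats::rnorm(nG * nCond, 0, config$noiseSd),
                                  nG, nCond)
            pv <- stats::pnorm(fd / config$noiseSd, lower.tail = FALSE)
            mask <- matrix(stats::runif(nG * nCond) < config$missingRate,
                           nG, nCond)
            fd[mask] <- NA_real_
            pv[mask] <- NA_real_
            dimnames(fd) <- dimnames(pv) <- list(genes, condIds)
            FitnessDataset(fd, pv, conditions, zyg)
        }
        list(het = buildDs(signalHet, "heterozygous"),
             hom = buildDs(signalHom, "homozygous"))
    })
}

#' Sample a known-interaction set from the planted truth
#'
#' Stands in for an expert-curated positive interaction list: positives
#' are drawn from the planted (compound, target) pairs without
#' replacement. Deterministic given the seed.
#'
#' @param truth planted-truth object.
#' @param nPositive number of positives to draw (at most the number of
#'   planted pairs).
#' @param seed integer RNG seed.
#' @return interaction data.frame (columns compound_id, gene_id, label,
#'   source).
#' @export
generateKnownInteractions <- function(truth, nPositive, seed) {
    planted <- truth$planted
    if (nPositive > nrow(planted))
        stop("nPositive exceeds the number of planted pairs")
    withr::with_seed(seed, {
        take <- sample(nrow(planted), nPositive)
        out <- planted[sort(take), c("compound_id", "gene_id")]
        out$label <- rep("positive", nrow(out))
        out$source <- rep("planted", nrow(out))
        rownames(out) <- NULL
        validateInteractions(out)
        out
    })
}

#' Simulate a complete chemogenomic study with planted ground truth
#'
#' Orchestrates the generators: gene annotations/complexes/reference
#' network, the compound library, the family-to-module and planted
#' target assignments, MDR genes, and the two fitness datasets. Three
#' sub-seeds derived from \code{seed} by fixed small offsets drive the
#' component generators, so the whole simulation is bit-reproducible.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer RNG seed (keep below 2^31 - 10).
#' @return list with elements \code{het}, \code{hom}
#'   (\linkS4class{FitnessDataset}), \code{annotations},
#'   \code{complexes}, \code{referenceNetwork}, \code{compounds},
#'   \code{fingerprints} and \code{truth} (planted pairs, module and
#'   family assignments, MDR genes, family ATC classes, config echo).
#' @export
simulateChemogenomics <- function(config = syntheticConfig(), seed = 1L) {
    geneSide <- generateGeneAnnotations(config, seed)
    lib <- generateCompoundLibrary(config, seed + 1L)
    truth <- withr::with_seed(seed + 2L, {
        famIds <- names(lib$familyCores)
        eligible <- names(geneSide$complexes)
        if (length(eligible) < length(famIds))
            stop("need at least as many complexes as compound families")
        moduleOfFamily <- stats::setNames(
            sample(eligible, length(famIds)), famIds)
        familyTarget <- vapply(famIds, function(f) {
            members <- geneSide$complexes[[moduleOfFamily[[f]]]]
            members[sample.int(length(members), 1L)]
        }, "")
        planted <- data.frame(
            compound_id = names(lib$family),
            gene_id = unname(familyTarget[lib$family]),
            stringsAsFactors = FALSE)
        genes <- geneSide$annotations$gene_id
        mdrGenes <- sample(genes, config$nMdrGenes)
        mdrResponse <- stats::setNames(lapply(mdrGenes, function(g)
            sample(lib$compounds$compound_id,
                   round(config$mdrCompoundFraction * config$nCompounds))),
            mdrGenes)
        list(planted = planted,
             geneModule = geneSide$geneModule,
             compoundFamily = lib$family,
             moduleOfFamily = moduleOfFamily,
             familyTarget = familyTarget,
             mdrGenes = mdrGenes,
             mdrResponse = mdrResponse,
             familyAtc = lib$familyAtc,
             complexes = geneSide$complexes,
             genes = genes,
             compounds = lib$compounds$compound_id,
             config = unclass(config))
    })
    fit <- generateFitnessData(config, truth, seed + 3L)
    list(het = fit$het, hom = fit$hom,
         annotations = geneSide$annotations,
         complexes = geneSide$complexes,
         referenceNetwork = geneSide$referenceNetwork,
         compounds = lib$compounds,
         fingerprints = lib$fingerprints,
         truth = truth)
}
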