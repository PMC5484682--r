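test_that("generation is bitwise-deterministic given the seed", {
    sp <- small_spec(seed = 7L)
    d1 <- generateDiscovery(sp)
    d2 <- generateDiscovery(sp)
    expect_identical(assay(d1$mirna, "exprs"), assay(d2$mirna, "exprs"))
    expect_identical(assay(d1$gene, "exprs"), assay(d2$gene, "exprs"))
    expect_identical(d1$truth@plantedPairs, d2$truth@plantedPairs)
    expect_identical(generateTargetTable(d1$truth, sp),
                     generateTargetTable(d2$truth, sp))
    d3 <- generateDiscovery(small_spec(seed = 8L))
    expect_false(identical(assay(d1$mirna, "exprs"),
                           assay(d3$mirna, "exprs")))
})

test_that("cohort geometry matches the configured group sizes", {
    d <- generateDiscovery(small_spec(seed = 2L))
    expect_equal(ncol(d$mirna), 35L + 17L + 13L)
    expect_equal(ncol(d$gene), 35L + 17L + 22L)
    expect_equal(length(intersect(colnames(d$mirna), colnames(d$gene))),
                 35L + 17L + 13L)
    expect_equal(as.integer(table(colData(d$gene)$group)[c("HC", "US", "CS")]),
                 c(35L, 17L, 22L))
    # planted pairs are within the signal sets
    expect_true(all(d$truth@plantedPairs$mirna_id %in%
                    d$truth@signalMirnas))
    expect_true(all(d$truth@plantedPairs$gene_symbol %in%
                    d$truth@signalGenes))
})

test_that("zero coupling yields null planted-pair correlation on average", {
    rhos <- vapply(seq_len(200), function(s) {
        sp <- syntheticSpec(nMirnaFeatures = 2L, nGeneFeatures = 2L,
                            nSignalMirnas = 1L, targetsPerMirna = 1L,
                            couplingStrength = 0, nDirectGenes = 0L,
                            nDecoyPredictions = 0L, seed = s)
        d <- generateDiscovery(sp)
        pp <- d$truth@plantedPairs
        shared <- intersect(colnames(d$mirna), colnames(d$gene))
        spearmanRho(assay(d$mirna, "exprs")[pp$mirna_id[1], shared],
                    assay(d$gene, "exprs")[pp$gene_symbol[1], shared])$rho
    }, numeric(1))
    se <- sd(rhos) / sqrt(length(rhos))
    expect_lt(abs(mean(rhos)), 3 * se)
})

test_that("strong planted severity effects produce strong miRNA correlations", {
    hits <- vapply(seq_len(200), function(s) {
        sp <- syntheticSpec(nMirnaFeatures = 4L, nGeneFeatures = 4L,
                            nSignalMirnas = 2L, targetsPerMirna = 1L,
                            nDirectGenes = 0L,
                            severityEffect = 2, noiseSd = 1, seed = s)
        d <- generateDiscovery(sp)
        sev <- colData(d$mirna)$severity
        all(vapply(d$truth@signalMirnas, function(m)
            abs(spearmanRho(assay(d$mirna, "exprs")[m, ], sev)$rho) > 0.5,
            logical(1)))
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("target tables separate planted and decoy scores at the cutoff", {
    sp <- small_spec(seed = 5L)
    d <- generateDiscovery(sp)
    tab <- generateTargetTable(d$truth, sp)
    expect_true(all(tab$mirsvr_score[tab$planted] <= -1.2))
    expect_true(all(tab$mirsvr_score[!tab$planted] > -1.2))
    expect_equal(sum(tab$planted), nrow(d$truth@plantedPairs))
    expect_equal(sum(!tab$planted), 30L)

    sp0 <- small_spec(seed = 5L, nDecoyPredictions = 0L)
    tab0 <- generateTargetTable(generateDiscovery(sp0)$truth, sp0)
    expect_equal(nrow(tab0), nrow(d$truth@plantedPairs))
})

test_that("validation cohorts are null at shift 0 and separable at shift 5", {
    sig <- Signature("toy", "mRNA", paste0("g", 1:5),
                     c(0.5, -0.4, 0.3, 0.6, -0.2))
    aucs <- vapply(seq_len(500), function(s) {
        v <- generateValidation(sig, 20, 20, shift = 0, seed = s,
                                nFeatures = 10L)
        rocAuc(scoreCohort(v, sig), colData(v)$severity)$auc
    }, numeric(1))
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - 0.5), 3 * se)

    perfect <- vapply(seq_len(200), function(s) {
        v <- generateValidation(sig, 8, 8, shift = 5, noiseSd = 1,
                                seed = s, nFeatures = 10L)
        rocAuc(scoreCohort(v, sig), colData(v)$severity)$auc == 1
    }, logical(1))
    expect_gte(mean(perfect), 0.99)

    v1 <- generateValidation(sig, 8, 8, shift = 2, seed = 3L)
    v2 <- generateValidation(sig, 8, 8, shift = 2, seed = 3L)
    expect_identical(assay(v1, "exprs"), assay(v2, "exprs"))
})

test_that("the screen recovers planted miRNAs with the correct sign", {
    res <- lapply(seq_len(10), function(s) {
        d <- generateDiscovery(small_spec(seed = 100L + s))
        scr <- suppressWarnings(screenFeatures(d$mirna, alpha = 0.05))
        flagged <- scr$feature_id
        planted <- d$truth@signalMirnas
        sens <- mean(planted %in% flagged)
        fdp <- if (length(flagged)) mean(!flagged %in% planted) else 0
        signs_ok <- {
            hit <- intersect(flagged, planted)
            all(sign(scr$rho[match(hit, scr$feature_id)]) ==
                d$truth@mirnaDirection[hit])
        }
        c(sens = sens, fdp = fdp, signs = signs_ok)
    })
    m <- colMeans(do.call(rbind, res))
    expect_gte(m[["sens"]], 0.9)
    expect_lte(m[["fdp"]], 0.1)
    expect_gte(m[["signs"]], 0.95)
})

test_that("spec validation rejects impossible designs", {
    expect_error(syntheticSpec(noiseSd = 0), "noiseSd")
    expect_error(syntheticSpec(nSignalMirnas = 10, nMirnaFeatures = 5),
                 "signal miRNAs")
    expect_error(syntheticSpec(nGeneFeatures = 4, nSignalMirnas = 8,
                               targetsPerMirna = 2), "target genes")
})
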