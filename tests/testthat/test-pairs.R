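test_that("mirSVR filter is inclusive at the cutoff and idempotent", {
    tab <- data.frame(mirna_id = c("m1", "m2", "m3"),
                      gene_symbol = c("g1", "g2", "g3"),
                      mirsvr_score = c(-1.201, -1.19, -1.2))
    out <- filterPredictions(tab, cutoff = -1.2)
    expect_setequal(out$gene_symbol, c("g1", "g3"))
    expect_equal(filterPredictions(out, cutoff = -1.2), out)
})

test_that("candidate pairs require both members to be differentially expressed", {
    tab <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      gene_symbol = c("g1", "g2", "g1"),
                      mirsvr_score = rep(-1.5, 3))
    mscr <- data.frame(feature_id = "m1", rho = 0.5)
    gscr <- data.frame(feature_id = "g1", rho = -0.5)
    out <- candidatePairs(tab, mscr, gscr)
    expect_equal(nrow(out), 1L)
    expect_equal(out$mirna_id, "m1")
    expect_equal(nrow(candidatePairs(tab, mscr[0, ], gscr)), 0L)
})

test_that("exact anti-correlation is retained with rho -1", {
    n <- 10
    m <- matrix(seq_len(n), 1, n,
                dimnames = list("m1", paste0("s", 1:n)))
    g <- matrix(-seq_len(n), 1, n,
                dimnames = list("g1", paste0("s", 1:n)))
    cand <- data.frame(mirna_id = "m1", gene_symbol = "g1",
                       mirsvr_score = -1.5)
    out <- pairAnticorrelation(cand, make_se(m, platform = "miRNA"),
                               make_se(g))
    expect_equal(nrow(out), 1L)
    expect_equal(out$pair_rho, -1)
})

test_that("independent decoy candidates are almost never retained", {
    false_hits <- vapply(seq_len(30), function(s) {
        set.seed(900 + s)
        n <- 40
        mv <- matrix(rnorm(20 * n), 20, n,
                     dimnames = list(sprintf("m%02d", 1:20),
                                     sprintf("s%02d", 1:n)))
        gv <- matrix(rnorm(20 * n), 20, n,
                     dimnames = list(sprintf("g%02d", 1:20),
                                     sprintf("s%02d", 1:n)))
        cand <- data.frame(
            mirna_id = rep(rownames(mv), each = 10),
            gene_symbol = rep(rownames(gv)[1:10], 20),
            mirsvr_score = -1.5)
        nrow(pairAnticorrelation(cand, make_se(mv, platform = "miRNA"),
                                 make_se(gv), alpha = 0.005))
    }, numeric(1))
    expect_lte(mean(false_hits), 1)
})

test_that("pair retention is independent of candidate ordering", {
    d <- generateDiscovery(small_spec(seed = 21L))
    sp <- small_spec(seed = 21L)
    tab <- generateTargetTable(d$truth, sp)
    ms <- suppressWarnings(screenFeatures(d$mirna, 0.05))
    gs <- suppressWarnings(screenFeatures(d$gene, 5e-4))
    cand <- candidatePairs(filterPredictions(tab), ms, gs)
    base <- pairAnticorrelation(cand, d$mirna, d$gene)
    perm <- cand[rev(seq_len(nrow(cand))), ]
    out <- pairAnticorrelation(perm, d$mirna, d$gene)
    key <- function(df) {
        df <- df[order(df$mirna_id, df$gene_symbol), ]
        rownames(df) <- NULL
        df
    }
    expect_equal(key(out), key(base))
})

test_that("with all features DE and no decoys the candidates are the planted pairs", {
    sp <- small_spec(seed = 22L, nDecoyPredictions = 0L)
    d <- generateDiscovery(sp)
    tab <- generateTargetTable(d$truth, sp)
    all_m <- data.frame(feature_id = rownames(d$mirna), rho = 0.1)
    all_g <- data.frame(feature_id = rownames(d$gene), rho = 0.1)
    cand <- candidatePairs(filterPredictions(tab), all_m, all_g)
    expect_equal(key <- paste(cand$mirna_id, cand$gene_symbol),
                 paste(d$truth@plantedPairs$mirna_id,
                       d$truth@plantedPairs$gene_symbol))
})

test_that("derived signatures collect unique members with screen rho values", {
    pairs <- data.frame(mirna_id = c("m1", "m1", "m2"),
                        gene_symbol = c("g1", "g2", "g3"),
                        mirsvr_score = -1.5, pair_rho = -0.5,
                        pair_adj_p = 0.001)
    mscr <- data.frame(feature_id = c("m2", "m1"), rho = c(-0.4, 0.35))
    gscr <- data.frame(feature_id = c("g3", "g2", "g1"),
                       rho = c(-0.45, -0.5, -0.55))
    sigs <- deriveSignatures(pairs, mscr, gscr)
    expect_equal(featureIds(sigs$mirna), c("m1", "m2"))
    expect_equal(unname(featureRho(sigs$mirna)), c(0.35, -0.4))
    expect_equal(featureIds(sigs$gene), c("g1", "g2", "g3"))
    expect_equal(unname(featureRho(sigs$gene)), c(-0.55, -0.5, -0.45))
    # single pair gives two singletons
    s1 <- deriveSignatures(pairs[1, ], mscr, gscr)
    expect_equal(length(s1$mirna), 1L)
    expect_equal(length(s1$gene), 1L)
    # missing screen record errors
    expect_error(deriveSignatures(pairs, mscr[2, , drop = FALSE], gscr),
                 "m2")
})

test_that("the reference pair table reproduces the published signature sizes", {
    msig <- sarcoidosisFixture("mirna_signature")
    gsig <- sarcoidosisFixture("gene_signature")
    sigs <- deriveSignatures(
        sarcoidosisFixture("pairs"),
        data.frame(feature_id = featureIds(msig), rho = featureRho(msig)),
        data.frame(feature_id = featureIds(gsig), rho = featureRho(gsig)))
    expect_equal(length(sigs$mirna), 8L)
    expect_equal(length(sigs$gene), 17L)
    expect_setequal(featureIds(sigs$mirna), featureIds(msig))
    expect_setequal(featureIds(sigs$gene), featureIds(gsig))
})
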