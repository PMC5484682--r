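test_that("AUC matches hand values, the tie rule, and the rank formula", {
    expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
    expect_equal(rocAuc(rep(2, 6), rep(c(FALSE, TRUE), 3))$auc, 0.5)
    expect_equal(rocAuc(c(1, 2, 1.5, 3),
                        c("control", "control", "case", "case"))$auc, 0.75)
    expect_error(rocAuc(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("the ROC curve runs monotonically from (0,0) to (1,1)", {
    set.seed(70)
    for (i in 1:10) {
        n <- sample(6:30, 1)
        s <- sample(rnorm(10), n, replace = TRUE)  # forces ties
        lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(lab) || all(lab)) next
        cv <- rocAuc(s, lab)$curve
        expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
        expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
        expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    }
})

test_that("AUC agrees with brute force and is antisymmetric under negation", {
    set.seed(71)
    for (i in 1:200) {
        n <- sample(4:30, 1)
        s <- round(rnorm(n), sample(0:2, 1))
        lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(lab) || all(lab)) next
        a <- rocAuc(s, lab)$auc
        expect_equal(a, oracle_auc(s, lab))
        expect_equal(a + rocAuc(-s, lab)$auc, 1)
    }
})

test_that("group t-test matches the closed-form Welch statistic", {
    a <- c(0, 0, 0.01)
    b <- c(10, 10, 10.01)
    out <- groupTtest(c(b, a), rep(c(TRUE, FALSE), each = 3))
    ref <- oracle_welch(b, a)
    expect_equal(out$t, ref$t)
    expect_equal(out$p, ref$p)
    expect_lt(out$p, 1e-4)
    # identical group distributions: t = 0, p = 1
    same <- groupTtest(c(1, 2, 3, 1, 2, 3),
                       rep(c(TRUE, FALSE), each = 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    # swapping labels flips the sign only
    sw <- groupTtest(c(b, a), rep(c(FALSE, TRUE), each = 3))
    expect_equal(sw$t, -out$t)
    expect_equal(sw$p, out$p)
})

test_that("severity trend handles group ties through mid-ranks", {
    out <- severityTrend(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 1, 2, 2))
    expect_equal(out$rho, oracle_spearman(1:6, c(0, 0, 1, 1, 2, 2))$rho)
    expect_equal(round(out$rho, 4), 0.9562)
    codes <- c(0, 0, 1, 1, 2, 2)
    expect_equal(severityTrend(codes, codes)$rho, 1, tolerance = 1e-12)
    expect_error(severityTrend(rep(1, 6), c(0, 0, 1, 1, 2, 2)),
                 "constant")
})

test_that("PCA in signature space has the documented structure", {
    # two perfectly correlated features: second eigenvalue 0
    vals <- rbind(f1 = c(0, 1, 2, 3), f2 = c(0, 2, 4, 6))
    colnames(vals) <- paste0("s", 1:4)
    sig <- Signature("toy", "mRNA", c("f1", "f2"), c(0.5, 0.5))
    out <- pcaSignature(make_se(vals), sig)
    expect_equal(out$eigenvalues[2], 0, tolerance = 1e-12)
    expect_true(diff(out$eigenvalues) <= 0)

    # anti-correlated pair: PC1 carries the total variance
    vals2 <- rbind(f1 = c(0, 1, 2), f2 = c(0, -1, -2))
    colnames(vals2) <- paste0("s", 1:3)
    out2 <- pcaSignature(make_se(vals2), sig)
    expect_equal(out2$eigenvalues[1], sum(out2$eigenvalues))
    expect_equal(out2$var_explained[1], 1)

    # sign convention: first feature loading >= 0 so scores are reproducible
    set.seed(72)
    vals3 <- matrix(rnorm(60), 6, 10,
                    dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
    sig3 <- Signature("toy", "mRNA", paste0("f", 1:6), rep(0.5, 6))
    base <- pcaSignature(make_se(vals3), sig3)
    perm <- sample(6)
    sig_p <- Signature("toy", "mRNA", paste0("f", 1:6)[perm],
                       rep(0.5, 6))
    out_p <- pcaSignature(make_se(vals3), sig_p)
    expect_equal(abs(out_p$sample_scores), abs(base$sample_scores),
                 ignore_attr = TRUE)
    expect_equal(out_p$eigenvalues, base$eigenvalues)
})

test_that("spearman agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(73)
    # cross-check AUC against pROC on random instances
    for (i in 1:25) {
        n <- sample(8:40, 1)
        s <- round(rnorm(n), 1)
        lab <- sample(c(0, 1), n, replace = TRUE)
        if (length(unique(lab)) < 2) next
        ref <- as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                              direction = "<")))
        expect_equal(rocAuc(s, lab)$auc, ref)
    }
})
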