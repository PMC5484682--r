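test_that("presence filter uses an inclusive two-thirds boundary", {
    vals <- matrix(rnorm(9), 3, 3,
                   dimnames = list(c("all", "one", "two"), paste0("s", 1:3)))
    mask <- rbind(all = c(TRUE, TRUE, TRUE),
                  one = c(TRUE, FALSE, FALSE),
                  two = c(TRUE, TRUE, FALSE))
    colnames(mask) <- colnames(vals)
    se <- make_se(vals)
    out <- presenceFilter(se, mask = mask)
    expect_identical(rownames(out), c("all", "two"))
    expect_identical(colnames(out), colnames(vals))
    # misaligned mask
    expect_error(presenceFilter(se, mask = mask[, c(2, 1, 3)]),
                 "not aligned")
})

test_that("spearmanRho matches hand values and errors on degenerate input", {
    expect_equal(spearmanRho(1:4, c(10, 20, 30, 40))$rho, 1)
    expect_equal(spearmanRho(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)
    expect_error(spearmanRho(1:5, rep(2, 5)), "constant")
    expect_error(spearmanRho(1:3, 1:3), "at least 4")
    expect_error(spearmanRho(1:4, 1:5), "equal length")
})

test_that("spearmanRho is invariant under strictly increasing transforms", {
    set.seed(42)
    for (i in 1:20) {
        x <- rnorm(12)
        y <- sample(rep(0:2, 4))
        base <- spearmanRho(x, y)
        expect_equal(spearmanRho(exp(x), y), base)
        expect_equal(spearmanRho(x^3 + 5 * x, 10 * y + 2), base)
    }
})

test_that("negating severity negates rho and preserves p-values", {
    set.seed(43)
    x <- rnorm(15)
    y <- sample(rep(0:2, 5))
    a <- spearmanRho(x, y)
    b <- spearmanRho(x, -y)
    expect_equal(b$rho, -a$rho)
    expect_equal(b$p_value, a$p_value)
})

test_that("bhAdjust reproduces the step-up definition and its bounds", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(44)
    for (i in 1:50) {
        p <- runif(sample(1:50, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, oracle_bh(p))
        expect_true(all(adj >= p) && all(adj <= 1))
    }
    expect_error(bhAdjust(c(0.5, 0)), "0, 1")
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("screenFeatures finds a perfect monotone feature among noise", {
    set.seed(45)
    n <- 30
    sev <- rep(0:2, each = 10)
    vals <- matrix(rnorm(200 * n), 200, n,
                   dimnames = list(sprintf("f%03d", 1:200),
                                   sprintf("s%02d", 1:n)))
    vals["f001", ] <- sev
    se <- make_se(vals, group = c("HC", "US", "CS")[sev + 1])
    out <- screenFeatures(se, alpha = 0.05)
    expect_true("f001" %in% out$feature_id)
    expect_equal(out$rho[out$feature_id == "f001"], 1)
    expect_equal(out$direction[out$feature_id == "f001"], "up")
    expect_true(all(out$adj_p >= out$p_value))
    expect_equal(attr(out, "n_family"), 200L)
})

test_that("alpha = 1 returns every non-constant feature", {
    set.seed(46)
    vals <- matrix(rnorm(40), 4, 10,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
    vals[4, ] <- 7  # constant
    se <- make_se(vals, group = rep(c("HC", "US"), 5))
    expect_warning(out <- screenFeatures(se, alpha = 1), "constant")
    expect_setequal(out$feature_id, paste0("f", 1:3))
})

test_that("screen output is invariant to sample and feature reordering", {
    set.seed(47)
    n <- 24
    sev <- sample(rep(0:2, 8))
    vals <- matrix(rnorm(50 * n), 50, n,
                   dimnames = list(sprintf("f%02d", 1:50),
                                   sprintf("s%02d", 1:n)))
    vals[1:5, ] <- vals[1:5, ] + 2 * rep(sev, each = 5)
    grp <- c("HC", "US", "CS")[sev + 1]
    se <- make_se(vals, group = grp)
    base <- screenFeatures(se, alpha = 0.05)

    perm_s <- sample(n)
    se_s <- make_se(vals[, perm_s], group = grp[perm_s])
    expect_equal(screenFeatures(se_s, alpha = 0.05), base,
                 ignore_attr = TRUE)

    perm_f <- sample(50)
    se_f <- make_se(vals[perm_f, ], group = grp)
    out_f <- screenFeatures(se_f, alpha = 0.05)
    ord <- match(base$feature_id, out_f$feature_id)
    expect_equal(out_f[ord, ], base, ignore_attr = TRUE)
})

test_that("screenFeatures validates inputs", {
    vals <- matrix(rnorm(20), 2, 10,
                   dimnames = list(c("a", "b"), paste0("s", 1:10)))
    se <- make_se(vals)
    expect_error(screenFeatures(se), "severity")
    se2 <- make_se(vals, group = rep(c("HC", "US"), 5))
    expect_error(screenFeatures(se2, alpha = 0), "alpha")
    expect_error(screenFeatures(se2, alpha = 1.5), "alpha")
})
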