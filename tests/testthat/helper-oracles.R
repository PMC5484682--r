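# Brute-force reference implementations, written independently of the
# package code paths they check.

# Mid-ranks by explicit tie-group averaging (no call to rank()).
oracle_midrank <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
        below <- sum(x < x[i])
        ties <- sum(x == x[i])
        # average of positions below+1 ... below+ties
        out[i] <- below + (ties + 1) / 2
    }
    out
}

# Spearman rho as the Pearson correlation of mid-ranks, computed from the
# raw sum formulas, with the asymptotic two-sided t p-value.
oracle_spearman <- function(x, y) {
    rx <- oracle_midrank(x)
    ry <- oracle_midrank(y)
    n <- length(x)
    sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
    sxx <- sum((rx - mean(rx))^2)
    syy <- sum((ry - mean(ry))^2)
    rho <- sxy / sqrt(sxx * syy)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Literal step-up definition: adj_(i) = min over j >= i of min(1, p_(j)*m/j),
# mapped back to input order.
oracle_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adj_sorted <- numeric(m)
    for (i in seq_len(m)) {
        vals <- vapply(i:m, function(j) min(1, sorted[j] * m / j),
                       numeric(1))
        adj_sorted[i] <- min(vals)
    }
    adj <- numeric(m)
    adj[ord] <- adj_sorted
    adj
}

# AUC by exhaustive pairwise comparison with half credit for ties.
oracle_auc <- function(scores, case) {
    pos <- scores[case]
    neg <- scores[!case]
    total <- 0
    for (p in pos)
        for (q in neg)
            total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
}

# Welch two-sample t-test from the closed form.
oracle_welch <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df))
}
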