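# Random-signature resampling benchmarks: compare a signature's summed AUC
# across validation cohorts against size-matched signatures drawn from a
# feature pool (whole feature universe, or the severity-related pool).

#' Summed AUC of a signature over validation cohorts
#'
#' Scores every cohort with the signature (drop policy for missing
#' features) and sums the resulting AUCs, cases positive.
#'
#' @param signature A [Signature-class].
#' @param cohorts List of annotated SummarizedExperiments with binary
#'   colData \code{severity} (0 = control, 1 = case).
#' @return The sum of AUC, in \eqn{[0, length(cohorts)]}.
#' @export
signatureAucSum <- function(signature, cohorts) {
    stopifnot(length(cohorts) >= 1L)
    sum(vapply(cohorts, function(se) {
        sc <- suppressWarnings(scoreCohort(se, signature,
                                           missing = "drop"))
        rocAuc(sc, colData(se)$severity)$auc
    }, numeric(1L)))
}

#' Draw size-matched random signatures from a pool
#'
#' Each draw selects \code{k} distinct features uniformly without
#' replacement.  A random signature needs a severity-correlation sign per
#' feature to be scorable: when \code{signs} (a named vector, e.g. screen
#' rho values) is supplied, each drawn feature takes the sign of its entry;
#' otherwise features carry a provisional +1 and are expected to be
#' oriented on the fly against each cohort's labels at evaluation time
#' (see [runResamplingTest()]).
#'
#' @param pool Character vector of candidate feature ids.
#' @param k Signature size.
#' @param nResamples Number of draws.
#' @param seed Integer seed; draws are deterministic given it.
#' @param signs Optional named numeric vector of orientation values.
#' @return List of [Signature-class] objects, length \code{nResamples}.
#' @export
drawRandomSignatures <- function(pool, k, nResamples, seed = 1L,
                                 signs = NULL) {
    if (length(pool) < k)
        stop("pool smaller than the signature size", call. = FALSE)
    stopifnot(nResamples >= 1L)
    withr::with_seed(as.integer(seed), {
        draws <- lapply(seq_len(nResamples),
                        function(i) sample(pool, k))
    })
    lapply(seq_along(draws), function(i) {
        ids <- draws[[i]]
        r <- if (is.null(signs)) rep(1, k)
             else {
                 v <- sign(signs[ids])
                 v[!is.finite(v) | v == 0] <- 1
                 unname(v)
             }
        Signature(sprintf("random-%d", i), "mRNA", ids, r)
    })
}

#' Right-tailed empirical p-value with add-one correction
#'
#' \eqn{p = (\#\{draws \ge observed\} + 1) / (n + 1)}: draws tied with the
#' observed value count toward the right tail (conservative), and the
#' add-one correction keeps p strictly positive, so the smallest
#' achievable p at 1,000 resamples is 1/1001.
#'
#' @param observed Observed statistic.
#' @param null_draws Numeric vector of null statistics, length >= 1.
#' @return The empirical p-value in (0, 1].
#' @examples
#' empiricalPRight(2.5, c(1, 2, 3, 4))  # 0.6
#' @export
empiricalPRight <- function(observed, null_draws) {
    if (!length(null_draws))
        stop("empty null distribution", call. = FALSE)
    (sum(null_draws >= observed) + 1) / (length(null_draws) + 1)
}

# AUC by the same midrank Mann-Whitney formula as rocAuc(), without the
# threshold-sweep curve — used in the resampling inner loop.
.fast_auc <- function(s, case) {
    r <- rank(s)
    n_pos <- sum(case)
    n_neg <- length(case) - n_pos
    (sum(r[case]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Sign-weighted z-score sum over a feature subset, identical to
# scoreCohort() on an all-present signature but without object overhead.
.fast_score <- function(vals, ids, w) {
    z <- scale(t(vals[ids, , drop = FALSE]))
    as.vector(z %*% w)
}

# Per-cohort orientation signs for every pool feature at once: the sign of
# the Spearman correlation with the labels is the sign of the inner product
# of centered mid-ranks.  Zero or degenerate correlations map to +1.
.orientation_signs <- function(se, ids) {
    vals <- assay(se, "exprs")[ids, , drop = FALSE]
    labr <- rank(as.numeric(colData(se)$severity))
    labr <- labr - mean(labr)
    rmat <- t(apply(vals, 1L, rank))
    s <- sign(as.vector((rmat - rowMeans(rmat)) %*% labr))
    s[s == 0] <- 1
    stats::setNames(s, ids)
}

#' Random-signature resampling test of signature performance
#'
#' Draws \code{nResamples} size-matched random signatures from a pool,
#' evaluates each by its summed AUC over the validation cohorts, and
#' returns the right-tailed empirical p-value of the observed signature's
#' summed AUC against that null distribution.
#'
#' Pool choice: \code{"genome"} uses every feature present in all cohort
#' matrices (the whole measured universe); \code{"disease_related"}
#' restricts to the features of the supplied severity-screen records (the
#' severity-associated pool), also intersected with the cohort features so
#' each draw is scorable.  Orientation of random features: the screen rho
#' sign when screen records are supplied, otherwise the sign of the
#' feature's Spearman correlation with each cohort's labels computed on
#' the fly — the random signatures' best-case orientation, which biases
#' the null upward and makes the test conservative.
#'
#' @param signature The observed [Signature-class].
#' @param cohorts List of annotated binary-label SummarizedExperiments.
#' @param pool Pool kind, \code{"genome"} or \code{"disease_related"}.
#' @param screen Screen records (data.frame with \code{feature_id},
#'   \code{rho}); required for the disease-related pool, optional
#'   orientation source for the genome pool.
#' @param nResamples Number of random signatures; default 1000.
#' @param seed Integer seed.
#' @return A [ResamplingOutcome-class].
#' @export
runResamplingTest <- function(signature, cohorts,
                              pool = c("genome", "disease_related"),
                              screen = NULL, nResamples = 1000L,
                              seed = 1L) {
    pool <- match.arg(pool)
    stopifnot(length(cohorts) >= 1L)
    universe <- Reduce(intersect, lapply(cohorts, rownames))
    if (pool == "disease_related") {
        if (is.null(screen))
            stop("the disease-related pool requires screen records",
                 call. = FALSE)
        ids <- intersect(screen$feature_id, universe)
    } else {
        ids <- universe
    }
    k <- length(signature)
    signs <- if (!is.null(screen))
        stats::setNames(screen$rho, screen$feature_id)
    observed <- signatureAucSum(signature, cohorts)
    draws <- drawRandomSignatures(ids, k, nResamples, seed = seed,
                                  signs = signs)
    orient <- if (is.null(signs))
        lapply(cohorts, .orientation_signs, ids = ids)
    cohort_vals <- lapply(cohorts, assay, "exprs")
    cohort_case <- lapply(cohorts,
                          function(se) colData(se)$severity > 0)
    null_draws <- vapply(draws, function(d) {
        fids <- featureIds(d)
        sum(vapply(seq_along(cohorts), function(ci) {
            w <- if (is.null(signs)) unname(orient[[ci]][fids])
                 else sign(featureRho(d))
            present <- fids %in% rownames(cohort_vals[[ci]])
            .fast_auc(.fast_score(cohort_vals[[ci]], fids[present],
                                  w[present]),
                      cohort_case[[ci]])
        }, numeric(1L)))
    }, numeric(1L))
    new("ResamplingOutcome",
        observed = observed,
        nullDraws = null_draws,
        pRight = empiricalPRight(observed, null_draws),
        pool = pool,
        nResamples = as.integer(nResamples),
        seed = as.integer(seed))
}
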