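# Signature performance: ROC/AUC (rank formulation), Welch t-test,
# severity trend, and PCA in signature space.

.case_flag <- function(labels) {
    if (is(labels, "SeverityScore"))
        stop("pass scores first, labels second", call. = FALSE)
    if (is.logical(labels)) return(labels)
    if (is.numeric(labels)) return(labels > 0)
    lab <- as.character(labels)
    code <- .severity_code(lab)
    if (length(unique(code)) != 2L)
        stop("labels must define exactly two classes", call. = FALSE)
    code > min(code)
}

.score_values <- function(scores) {
    if (is(scores, "SeverityScore")) sampleScores(scores)
    else as.numeric(scores)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted half, with
#' cases as the positive class and higher scores more disease-like; the
#' curve is a threshold sweep over the unique score values, from (0, 0) to
#' (1, 1).
#'
#' @param scores A [SeverityScore-class] or numeric vector.
#' @param labels Class labels aligned to \code{scores}: logical case
#'   indicator, numeric codes (case = positive), or
#'   \code{control}/\code{case} strings.
#' @return List with \code{auc}, \code{curve} (data.frame \code{fpr},
#'   \code{tpr}), \code{n_pos}, \code{n_neg}.
#' @examples
#' rocAuc(c(1, 2, 1.5, 3), c("control", "control", "case", "case"))$auc
#' @export
rocAuc <- function(scores, labels) {
    s <- .score_values(scores)
    case <- .case_flag(labels)
    if (length(s) != length(case))
        stop("scores and labels lengths differ", call. = FALSE)
    n_pos <- sum(case)
    n_neg <- sum(!case)
    if (n_pos == 0L || n_neg == 0L)
        stop("both classes must be non-empty", call. = FALSE)
    r <- rank(s)  # midranks give the half-credit tie rule
    auc <- (sum(r[case]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    thr <- sort(unique(s), decreasing = TRUE)
    curve <- data.frame(
        fpr = c(0, vapply(thr, function(t) mean(s[!case] >= t),
                          numeric(1L))),
        tpr = c(0, vapply(thr, function(t) mean(s[case] >= t),
                          numeric(1L))))
    list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg)
}

#' Two-group comparison of severity scores
#'
#' Welch (unequal-variance) two-sample two-sided t-test by default, cases
#' minus controls; set \code{welch = FALSE} for the pooled-variance
#' Student test.
#'
#' @inheritParams rocAuc
#' @param welch Use the Welch statistic (default) or pooled variance.
#' @return List with \code{t} and \code{p}.
#' @export
groupTtest <- function(scores, labels, welch = TRUE) {
    s <- .score_values(scores)
    case <- .case_flag(labels)
    if (sum(case) < 2L || sum(!case) < 2L)
        stop("need >= 2 samples per class", call. = FALSE)
    ht <- stats::t.test(s[case], s[!case], var.equal = !welch)
    list(t = unname(ht$statistic), p = ht$p.value)
}

#' Severity trend of a score
#'
#' Spearman rank correlation between the per-sample score and the ordinal
#' severity code (see [spearmanRho()]).
#'
#' @param scores A [SeverityScore-class] or numeric vector.
#' @param severity Integer severity codes (or an annotation DataFrame with
#'   a \code{severity} column) aligned to \code{scores}.
#' @return List with \code{rho} and \code{p_value}.
#' @export
severityTrend <- function(scores, severity) {
    s <- .score_values(scores)
    if (is(severity, "DataFrame") || is.data.frame(severity))
        severity <- severity$severity
    spearmanRho(s, as.numeric(severity))
}

#' PCA of a cohort in signature space
#'
#' Features are standardized (the signature mixes features of different
#' scales), then the sample covariance in feature space is
#' eigen-decomposed.  The component sign is fixed so that the loading of
#' the first signature feature present is non-negative.
#'
#' @param se SummarizedExperiment with an \code{exprs} assay.
#' @param signature A [Signature-class]; at least two features must be
#'   present in the matrix.
#' @return List with \code{sample_scores} (samples x 2), \code{eigenvalues}
#'   (first two component variances, nonincreasing) and \code{var_explained}.
#' @export
pcaSignature <- function(se, signature) {
    vals <- assay(se, "exprs")
    present <- intersect(featureIds(signature), rownames(vals))
    if (length(present) < 2L)
        stop("need >= 2 signature features present in the matrix",
             call. = FALSE)
    if (ncol(vals) < 3L)
        stop("need >= 3 samples", call. = FALSE)
    z <- vapply(present, function(f) standardizeFeature(vals[f, ]),
                numeric(ncol(vals)))
    pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    if (pc$sdev[1L] == 0)
        stop("degenerate matrix: zero total variance", call. = FALSE)
    k <- min(2L, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        if (rot[1L, j] < 0) {
            scores[, j] <- -scores[, j]
            rot[, j] <- -rot[, j]
        }
    }
    if (k < 2L) {  # pad a zero second component for 2-sample edge cases
        scores <- cbind(scores, 0)
        colnames(scores) <- c("PC1", "PC2")
    }
    ev <- pc$sdev^2
    ev2 <- c(ev, 0)[1:2]
    list(sample_scores = scores[, 1:2, drop = FALSE],
         eigenvalues = ev2,
         var_explained = ev2 / sum(ev))
}
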