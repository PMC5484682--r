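# Severity screen: rank-correlate each feature with ordinal severity,
# adjust with Benjamini-Hochberg, filter at a strict threshold.

#' Presence filter
#'
#' Retains features detected in at least \code{fraction} of samples
#' (inclusive boundary: a feature detected in exactly 2 of 3 samples passes
#' at the default two-thirds).  The sample set is unchanged.
#'
#' @param se SummarizedExperiment with assays \code{exprs} and (optionally)
#'   logical \code{detected}.
#' @param mask Optional logical matrix aligned to \code{se}; defaults to
#'   the \code{detected} assay, or all-true when neither exists.
#' @param fraction Required detected fraction, in (0, 1].
#' @return The filtered SummarizedExperiment.
#' @export
presenceFilter <- function(se, mask = NULL, fraction = 2 / 3) {
    stopifnot(fraction > 0, fraction <= 1)
    if (is.null(mask)) {
        mask <- if ("detected" %in% assayNames(se)) assay(se, "detected")
                else matrix(TRUE, nrow(se), ncol(se),
                            dimnames = dimnames(se))
    }
    if (!identical(dim(mask), dim(se)) ||
        !identical(rownames(mask), rownames(se)) ||
        !identical(colnames(mask), colnames(se)))
        stop("detection mask is not aligned to the expression matrix",
             call. = FALSE)
    keep <- rowSums(mask) / ncol(se) >= fraction
    se[keep, ]
}

#' Spearman rank correlation with asymptotic p-value
#'
#' Mid-rank (average ranks for ties) Pearson formulation with a two-sided
#' p-value from \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees
#' of freedom.  Ties dominate severity vectors (only three distinct
#' values), so the tie-free \eqn{\sum d^2} shortcut is deliberately not
#' used.  Delegates to \code{stats::cor.test(method = "spearman", exact =
#' FALSE)}, which implements exactly this formulation.
#'
#' @param x,y Equal-length numeric vectors, \code{n >= 4}, each
#'   non-constant.
#' @return List with elements \code{rho} and \code{p_value} (clamped away
#'   from zero so downstream adjustment stays in (0, 1]).
#' @examples
#' spearmanRho(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))$rho  # 0.6
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length", call. = FALSE)
    if (length(x) < 4L)
        stop("need at least 4 paired observations", call. = FALSE)
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("inputs must be finite", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: constant vector", call. = FALSE)
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate),
         p_value = max(ct$p.value, .Machine$double.xmin))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order; elementwise \code{>=} input
#'   and \code{<= 1}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p_values) {
    if (!length(p_values)) return(numeric())
    if (!all(is.finite(p_values)) || any(p_values <= 0) ||
        any(p_values > 1))
        stop("p-values must lie in (0, 1]", call. = FALSE)
    stats::p.adjust(p_values, method = "BH")
}

#' Screen features against ordinal severity
#'
#' One Spearman test per feature against the severity code, BH adjustment
#' over the whole feature family (every feature in \code{se}, i.e. the
#' post-presence-filter set), and a strict \code{adj_p < alpha} filter.
#' Constant features are assigned \code{rho = 0} and \code{p = 1}, kept in
#' the adjustment family, and excluded from the returned records with a
#' warning.
#'
#' @param se SummarizedExperiment whose colData carries \code{severity}
#'   (attach with [attachAnnotation()] or pass \code{annotation}).
#' @param alpha Strict significance threshold on the adjusted p-value, in
#'   (0, 1]; \code{alpha = 1} disables filtering and returns every
#'   non-constant feature.
#' @param annotation Optional annotation DataFrame to attach first.
#' @return data.frame with columns \code{feature_id}, \code{rho},
#'   \code{p_value}, \code{adj_p}, \code{direction} (\code{up}/\code{down})
#'   for the significant features, in feature order; attributes
#'   \code{n_family} (BH family size) and \code{alpha}.
#' @export
screenFeatures <- function(se, alpha = 0.05, annotation = NULL) {
    if (!is.null(annotation))
        se <- attachAnnotation(se, annotation)
    if (!"severity" %in% colnames(colData(se)))
        stop("no severity annotation on the matrix; see attachAnnotation()",
             call. = FALSE)
    if (alpha <= 0 || alpha > 1)
        stop("'alpha' must be in (0, 1]", call. = FALSE)
    sev <- colData(se)$severity
    if (length(unique(sev)) < 2L)
        stop("severity is constant across samples", call. = FALSE)
    vals <- assay(se, "exprs")
    if (!ncol(vals))
        stop("no overlapping samples", call. = FALSE)
    n_feat <- nrow(vals)
    rho <- numeric(n_feat)
    p <- rep(1, n_feat)
    constant <- logical(n_feat)
    for (i in seq_len(n_feat)) {
        v <- vals[i, ]
        if (stats::sd(v) == 0) {
            constant[i] <- TRUE
            next
        }
        st <- spearmanRho(v, sev)
        rho[i] <- st$rho
        p[i] <- st$p_value
    }
    if (any(constant))
        warning(sum(constant), " constant feature(s) excluded from the ",
                "screen (rho set to 0)", call. = FALSE)
    adj <- bhAdjust(p)
    keep <- !constant & (adj < alpha | alpha >= 1)
    out <- data.frame(
        feature_id = rownames(vals)[keep],
        rho = rho[keep],
        p_value = p[keep],
        adj_p = adj[keep],
        direction = ifelse(rho[keep] > 0, "up", "down"))
    rownames(out) <- NULL
    attr(out, "n_family") <- n_feat
    attr(out, "alpha") <- alpha
    out
}
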