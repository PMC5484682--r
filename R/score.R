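# The sign-weighted standardized-expression severity score: for a cohort
# expression matrix and a signature with severity correlations rho_i,
#   S_sample = sum_i sgn(rho_i) * (e_i - mu_i) / tau_i
# where mu_i and tau_i are the mean and (sample, n-1) standard deviation of
# feature i across all samples of the cohort being scored.

#' Standardize a feature across samples
#'
#' Centers to mean zero and scales to unit sample standard deviation
#' (denominator \code{n - 1}).
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return The z-scored vector.
#' @examples
#' standardizeFeature(c(0, 1, 2))  # -1 0 1
#' @export
standardizeFeature <- function(values) {
    if (length(values) < 2L)
        stop("need at least 2 values", call. = FALSE)
    if (!all(is.finite(values)))
        stop("values must be finite", call. = FALSE)
    tau <- stats::sd(values)
    if (tau == 0)
        stop("degenerate feature: zero variance", call. = FALSE)
    (values - mean(values)) / tau
}

#' Score a cohort with a signature
#'
#' Computes the per-sample severity score as the sum over signature
#' features of \code{sign(rho_i)} times the feature's z-score.
#' Standardization constants are computed on the cohort being scored,
#' across all of its samples (cases included) — a transductive design: no
#' training-set mean/SD is frozen.  Higher scores are more disease-like.
#'
#' @param se SummarizedExperiment with an \code{exprs} assay.
#' @param signature A [Signature-class].
#' @param missing Policy for signature features absent from the matrix:
#'   \code{"drop"} (default; drops them with a warning and records
#'   coverage — tolerant of cross-platform application) or \code{"error"}.
#' @return A [SeverityScore-class].
#' @examples
#' v <- generateValidation(sarcoidosisFixture("gene_signature"), 8, 8,
#'                         shift = 2, seed = 1)
#' scoreCohort(v, sarcoidosisFixture("gene_signature"))
#' @export
scoreCohort <- function(se, signature, missing = c("drop", "error")) {
    missing <- match.arg(missing)
    stopifnot(is(signature, "Signature"))
    vals <- assay(se, "exprs")
    ids <- featureIds(signature)
    absent <- setdiff(ids, rownames(vals))
    if (length(absent)) {
        if (missing == "error")
            stop("signature features absent from matrix: ",
                 paste(absent, collapse = ", "), call. = FALSE)
        warning("dropping ", length(absent), " signature feature(s) ",
                "absent from the matrix: ",
                paste(absent, collapse = ", "), call. = FALSE)
    }
    present <- setdiff(ids, absent)
    if (!length(present))
        stop("zero signature coverage on this matrix", call. = FALSE)
    w <- sign(featureRho(signature)[present])
    z <- vapply(present, function(f) standardizeFeature(vals[f, ]),
                numeric(ncol(vals)))
    score <- as.vector(z %*% w)
    names(score) <- colnames(vals)
    new("SeverityScore", score = score,
        signatureName = signatureName(signature),
        coverage = length(present) / length(ids),
        missingFeatures = absent)
}
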