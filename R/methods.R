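#' @rdname Signature-class
#' @export
setMethod("featureIds", "Signature", function(x) x@featureIds)

#' @rdname Signature-class
#' @export
setMethod("featureRho", "Signature", function(x) {
    stats::setNames(x@rho, x@featureIds)
})

#' @rdname Signature-class
#' @export
setMethod("signatureName", "Signature", function(x) x@name)

#' @rdname Signature-class
#' @export
setMethod("length", "Signature", function(x) length(x@featureIds))

#' @rdname Signature-class
#' @export
setMethod("show", "Signature", function(object) {
    cat(sprintf("Signature \"%s\" (%s platform, %d features)\n",
                object@name, object@platform, length(object@featureIds)))
    n <- min(5L, length(object@featureIds))
    lab <- sprintf("%s (rho=% .3f)", object@featureIds[seq_len(n)],
                   object@rho[seq_len(n)])
    cat("  ", paste(lab, collapse = ", "),
        if (length(object@featureIds) > n) ", ..." else "", "\n", sep = "")
})

#' @rdname SeverityScore-class
#' @export
setMethod("sampleScores", "SeverityScore", function(x) x@score)

#' @rdname SeverityScore-class
#' @export
setMethod("scoreCoverage", "SeverityScore", function(x) x@coverage)

#' @rdname SeverityScore-class
#' @export
setMethod("signatureName", "SeverityScore", function(x) x@signatureName)

#' @rdname SeverityScore-class
#' @export
setMethod("length", "SeverityScore", function(x) length(x@score))

#' @rdname SeverityScore-class
#' @export
setMethod("show", "SeverityScore", function(object) {
    cat(sprintf(
        "SeverityScore for signature \"%s\": %d samples, coverage %.2f\n",
        object@signatureName, length(object@score), object@coverage))
    cat("  score range: [", sprintf("%.3f", min(object@score)), ", ",
        sprintf("%.3f", max(object@score)), "]\n", sep = "")
    if (length(object@missingFeatures))
        cat("  missing features:",
            paste(object@missingFeatures, collapse = ", "), "\n")
})

#' @rdname ResamplingOutcome-class
#' @export
setMethod("observedStat", "ResamplingOutcome", function(x) x@observed)

#' @rdname ResamplingOutcome-class
#' @export
setMethod("nullDraws", "ResamplingOutcome", function(x) x@nullDraws)

#' @rdname ResamplingOutcome-class
#' @export
setMethod("pRight", "ResamplingOutcome", function(x) x@pRight)

#' @rdname ResamplingOutcome-class
#' @export
setMethod("show", "ResamplingOutcome", function(object) {
    cat(sprintf(
        "ResamplingOutcome (%s pool, %d resamples, seed %d)\n",
        object@pool, object@nResamples, object@seed))
    cat(sprintf("  observed sum of AUC: %.4f\n", object@observed))
    cat(sprintf("  null draws: mean %.4f, max %.4f\n",
                mean(object@nullDraws), max(object@nullDraws)))
    cat(sprintf("  right-tailed empirical P: %.4g\n", object@pRight))
})
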