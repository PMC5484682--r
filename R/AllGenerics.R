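#' @rdname Signature-class
#' @param x,object A package object.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname Signature-class
#' @export
setGeneric("featureRho", function(x) standardGeneric("featureRho"))

#' @rdname Signature-class
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname SeverityScore-class
#' @param x,object A package object.
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname SeverityScore-class
#' @export
setGeneric("scoreCoverage", function(x) standardGeneric("scoreCoverage"))

#' @rdname ResamplingOutcome-class
#' @param x,object A package object.
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname ResamplingOutcome-class
#' @export
setGeneric("nullDraws", function(x) standardGeneric("nullDraws"))

#' @rdname ResamplingOutcome-class
#' @export
setGeneric("pRight", function(x) standardGeneric("pRight"))
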