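#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
NULL

GROUP_CODES <- c(HC = 0L, US = 1L, CS = 2L, control = 0L, case = 1L)

#' Expression signature with severity-correlation weights
#'
#' A \code{Signature} is an ordered set of expression features (miRNAs or
#' gene symbols), each annotated with the Spearman correlation coefficient
#' \eqn{\rho_i} between its expression and ordinal disease severity.  Only
#' the sign of \eqn{\rho_i} enters the severity score; the magnitude is kept
#' for reporting.
#'
#' @slot name Character scalar, signature label.
#' @slot platform Either \code{"miRNA"} or \code{"mRNA"}.
#' @slot featureIds Character vector of unique feature identifiers.
#' @slot rho Numeric vector of severity-correlation coefficients, one per
#'   feature; finite, non-zero, in \eqn{[-1, 1]}.
#'
#' @seealso [scoreCohort()], [sarcoidosisFixture()]
#' @export
setClass("Signature",
    representation(
        name = "character",
        platform = "character",
        featureIds = "character",
        rho = "numeric"
    )
)

setValidity("Signature", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(object@platform) != 1L ||
        !object@platform %in% c("miRNA", "mRNA"))
        msg <- c(msg, "'platform' must be \"miRNA\" or \"mRNA\"")
    if (length(object@featureIds) < 1L)
        msg <- c(msg, "signature must contain at least one feature")
    if (anyDuplicated(object@featureIds))
        msg <- c(msg, "feature ids must be unique")
    if (length(object@rho) != length(object@featureIds))
        msg <- c(msg, "'rho' and 'featureIds' lengths differ")
    if (length(object@rho) &&
        (!all(is.finite(object@rho)) || any(object@rho == 0) ||
         any(abs(object@rho) > 1)))
        msg <- c(msg, "'rho' values must be finite, non-zero, in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a Signature
#'
#' @param name Signature label.
#' @param platform \code{"miRNA"} or \code{"mRNA"}.
#' @param featureIds Character vector of unique feature identifiers.
#' @param rho Numeric severity-correlation coefficients (non-zero), one per
#'   feature; the sign is the score weight.
#' @return A [Signature-class] object.
#' @examples
#' sig <- Signature("toy", "mRNA", c("STAT4", "ADORA3"), c(-0.5, 0.46))
#' featureIds(sig)
#' @export
Signature <- function(name, platform = c("miRNA", "mRNA"), featureIds, rho) {
    platform <- match.arg(platform)
    new("Signature", name = as.character(name), platform = platform,
        featureIds = as.character(featureIds), rho = as.numeric(rho))
}

#' Parameters of the synthetic cohort generator
#'
#' Encapsulates the study design emulated by [generateDiscovery()]: three
#' ordered severity groups (healthy control, uncomplicated, complicated),
#' planted monotone severity-associated miRNAs, target genes generated
#' conditionally on their regulating miRNA (hence negatively coupled), decoy
#' features, and the target-prediction table geometry.  The group-size
#' defaults (35/17/13 complicated on the miRNA platform, 35/17/22 on the
#' mRNA platform) reproduce the discovery-cohort layout assumed throughout.
#'
#' @slot nHC,nUS Integer counts of healthy controls / uncomplicated cases
#'   (shared by both platforms).
#' @slot nCSmirna,nCSgene Integer counts of complicated cases profiled on
#'   the miRNA and mRNA platforms; the first
#'   \code{min(nCSmirna, nCSgene)} complicated samples are shared.
#' @slot nMirnaFeatures,nGeneFeatures Total feature counts per platform.
#' @slot nSignalMirnas Number of miRNAs with a planted severity trend.
#' @slot targetsPerMirna Planted target genes per signal miRNA (targets are
#'   disjoint across miRNAs).
#' @slot severityEffect Per-severity-step shift of a signal miRNA's group
#'   mean, in units of \code{noiseSd}.
#' @slot couplingStrength Regression slope of a planted target gene on its
#'   miRNA's realized expression (negated), dimensionless.
#' @slot noiseSd Standard deviation of the Gaussian noise on log-scale
#'   expression.
#' @slot nDirectGenes Number of genes with a direct (miRNA-independent)
#'   severity trend of random direction — the analogue of the bulk of
#'   severity-associated genes that are not regulated by the screened
#'   miRNAs; they populate the disease-related resampling pool.
#' @slot nDecoyPredictions Number of random non-planted rows in the
#'   generated target-prediction table.
#' @slot detectionDropout Fraction of mask entries set undetected (0 gives
#'   an all-true detection mask).
#' @slot seed Integer seed; all draws come from one generator in a fixed
#'   documented order.
#' @export
setClass("SyntheticSpec",
    representation(
        nHC = "integer", nUS = "integer",
        nCSmirna = "integer", nCSgene = "integer",
        nMirnaFeatures = "integer", nGeneFeatures = "integer",
        nSignalMirnas = "integer", targetsPerMirna = "integer",
        severityEffect = "numeric", couplingStrength = "numeric",
        noiseSd = "numeric", nDirectGenes = "integer",
        nDecoyPredictions = "integer",
        detectionDropout = "numeric", seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    counts <- c(object@nHC, object@nUS, object@nCSmirna, object@nCSgene,
                object@nMirnaFeatures, object@nGeneFeatures,
                object@nSignalMirnas, object@targetsPerMirna)
    if (any(counts < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (object@nDecoyPredictions < 0L)
        msg <- c(msg, "'nDecoyPredictions' must be >= 0")
    if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
        msg <- c(msg, "'noiseSd' must be > 0")
    if (object@detectionDropout < 0 || object@detectionDropout >= 1)
        msg <- c(msg, "'detectionDropout' must be in [0, 1)")
    if (object@nSignalMirnas > object@nMirnaFeatures)
        msg <- c(msg, "more signal miRNAs than miRNA features")
    if (object@nDirectGenes < 0L)
        msg <- c(msg, "'nDirectGenes' must be >= 0")
    if (object@nSignalMirnas * object@targetsPerMirna +
        object@nDirectGenes > object@nGeneFeatures)
        msg <- c(msg, "more planted target genes than gene features")
    if (length(msg)) msg else TRUE
})

#' @param nHC,nUS,nCSmirna,nCSgene,nMirnaFeatures,nGeneFeatures,nSignalMirnas,targetsPerMirna,severityEffect,couplingStrength,noiseSd,nDirectGenes,nDecoyPredictions,detectionDropout,seed
#'   See the slot documentation in [SyntheticSpec-class].
#' @return A validated [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(seed = 7, nGeneFeatures = 500)
#' @rdname SyntheticSpec-class
#' @export
syntheticSpec <- function(nHC = 35L, nUS = 17L, nCSmirna = 13L, nCSgene = 22L,
                          nMirnaFeatures = 300L, nGeneFeatures = 2000L,
                          nSignalMirnas = 8L, targetsPerMirna = 2L,
                          severityEffect = 1.5, couplingStrength = 1,
                          noiseSd = 1, nDirectGenes = 150L,
                          nDecoyPredictions = 200L,
                          detectionDropout = 0, seed = 1L) {
    new("SyntheticSpec",
        nHC = as.integer(nHC), nUS = as.integer(nUS),
        nCSmirna = as.integer(nCSmirna), nCSgene = as.integer(nCSgene),
        nMirnaFeatures = as.integer(nMirnaFeatures),
        nGeneFeatures = as.integer(nGeneFeatures),
        nSignalMirnas = as.integer(nSignalMirnas),
        targetsPerMirna = as.integer(targetsPerMirna),
        severityEffect = as.numeric(severityEffect),
        couplingStrength = as.numeric(couplingStrength),
        noiseSd = as.numeric(noiseSd),
        nDirectGenes = as.integer(nDirectGenes),
        nDecoyPredictions = as.integer(nDecoyPredictions),
        detectionDropout = as.numeric(detectionDropout),
        seed = as.integer(seed))
}

#' Planted structure of a synthetic discovery cohort
#'
#' Records which features carry signal so that downstream recovery can be
#' scored against the truth.
#'
#' @slot signalMirnas Character ids of miRNAs with a planted severity trend.
#' @slot mirnaDirection Named numeric (+1/-1) planted trend direction per
#'   signal miRNA.
#' @slot plantedPairs data.frame with columns \code{mirna_id},
#'   \code{gene_symbol}: the true regulatory pairs.
#' @slot signalGenes Character ids of planted target genes.
#' @slot geneDirection Named numeric (+1/-1) expected severity direction of
#'   each signal gene (opposite to its miRNA's).
#' @slot directGenes Character ids of genes with a direct severity trend
#'   (no miRNA coupling).
#' @slot directDirection Named numeric (+1/-1) trend direction per direct
#'   gene.
#' @slot mirnaUniverse,geneUniverse All feature ids per platform (used to
#'   draw decoy predictions).
#' @export
setClass("GroundTruth",
    representation(
        signalMirnas = "character", mirnaDirection = "numeric",
        plantedPairs = "data.frame", signalGenes = "character",
        geneDirection = "numeric", directGenes = "character",
        directDirection = "numeric", mirnaUniverse = "character",
        geneUniverse = "character"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    pp <- object@plantedPairs
    if (!all(c("mirna_id", "gene_symbol") %in% names(pp)))
        msg <- c(msg, "'plantedPairs' needs columns mirna_id, gene_symbol")
    else {
        if (!all(pp$mirna_id %in% object@signalMirnas))
            msg <- c(msg, "planted pair miRNA outside signal set")
        if (!all(pp$gene_symbol %in% object@signalGenes))
            msg <- c(msg, "planted pair gene outside signal set")
    }
    if (!all(object@signalMirnas %in% object@mirnaUniverse))
        msg <- c(msg, "signal miRNAs outside the miRNA universe")
    if (!all(object@signalGenes %in% object@geneUniverse))
        msg <- c(msg, "signal genes outside the gene universe")
    if (length(msg)) msg else TRUE
})

#' Per-sample severity scores
#'
#' The result of applying a signature to a cohort: one dimensionless score
#' per sample (sum of sign-weighted feature z-scores), plus bookkeeping on
#' how much of the signature the cohort's platform actually covered.
#'
#' @slot score Named numeric vector, one score per sample.
#' @slot signatureName Label of the signature that was applied.
#' @slot coverage Fraction of signature features found in the matrix, in
#'   (0, 1].
#' @slot missingFeatures Ids of signature features absent from the matrix.
#' @export
setClass("SeverityScore",
    representation(
        score = "numeric", signatureName = "character",
        coverage = "numeric", missingFeatures = "character"
    )
)

setValidity("SeverityScore", function(object) {
    msg <- character()
    if (is.null(names(object@score)))
        msg <- c(msg, "'score' must be named by sample id")
    if (length(object@coverage) != 1L || object@coverage <= 0 ||
        object@coverage > 1)
        msg <- c(msg, "'coverage' must be a scalar in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Result of a random-signature resampling test
#'
#' Compares a signature's summed AUC across validation cohorts against
#' size-matched signatures drawn from a feature pool; \code{pRight} is the
#' add-one right-tailed empirical p-value.
#'
#' @slot observed Observed sum of AUC over cohorts.
#' @slot nullDraws Numeric vector of null sum-of-AUC values, one per
#'   resample.
#' @slot pRight Right-tailed empirical p,
#'   \eqn{(\#\{draws \ge observed\} + 1)/(n + 1)}.
#' @slot pool Either \code{"genome"} or \code{"disease_related"}.
#' @slot nResamples Number of null draws.
#' @slot seed Seed used for the draws.
#' @export
setClass("ResamplingOutcome",
    representation(
        observed = "numeric", nullDraws = "numeric", pRight = "numeric",
        pool = "character", nResamples = "integer", seed = "integer"
    )
)

setValidity("ResamplingOutcome", function(object) {
    msg <- character()
    if (length(object@nullDraws) != object@nResamples)
        msg <- c(msg, "'nullDraws' length must equal 'nResamples'")
    expect <- (sum(object@nullDraws >= object@observed) + 1) /
        (length(object@nullDraws) + 1)
    if (length(object@pRight) != 1L ||
        abs(object@pRight - expect) > 1e-12)
        msg <- c(msg, "'pRight' inconsistent with draws and observed value")
    if (!object@pool %in% c("genome", "disease_related"))
        msg <- c(msg, "'pool' must be \"genome\" or \"disease_related\"")
    if (length(msg)) msg else TRUE
})
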