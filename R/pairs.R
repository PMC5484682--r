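# Pair integration: mirSVR filter on predicted targets, intersection with
# the differential-expression screens, anti-correlation test, and
# derivation of the unique miRNA and gene signatures.

#' Filter target predictions by mirSVR score
#'
#' Retains predictions with \code{mirsvr_score <= cutoff}.  The comparison
#' is inclusive: reference pair tables contain scores printed at the cutoff
#' resolution (e.g. -1.201), and an exclusive rule at coarser print
#' precision could drop published pairs.
#'
#' @param predictions Target-prediction data.frame (\code{mirna_id},
#'   \code{gene_symbol}, \code{mirsvr_score}).
#' @param cutoff Score threshold; default -1.2, the conventional "top 5%
#'   of predictions" cutoff.
#' @return The retained rows.
#' @export
filterPredictions <- function(predictions, cutoff = -1.2) {
    stopifnot(all(is.finite(predictions$mirsvr_score)))
    out <- predictions[predictions$mirsvr_score <= cutoff, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Intersect predictions with the differential-expression screens
#'
#' Retains predictions whose miRNA passed the miRNA severity screen and
#' whose target gene passed the gene severity screen.
#'
#' @param predictions Target-prediction data.frame.
#' @param mirnaScreen,geneScreen Screen records from [screenFeatures()].
#' @return The retained prediction rows (candidate pairs).
#' @export
candidatePairs <- function(predictions, mirnaScreen, geneScreen) {
    keep <- predictions$mirna_id %in% mirnaScreen$feature_id &
        predictions$gene_symbol %in% geneScreen$feature_id
    out <- predictions[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Test candidate pairs for expression anti-correlation
#'
#' For each candidate pair, the Spearman correlation between miRNA and
#' target-gene expression is computed across the samples shared by the two
#' platforms; p-values are BH-adjusted over the candidate-pair family, and
#' pairs with \code{rho < 0} and \code{adj_p < alpha} (strict) are
#' retained.  Candidates referencing a feature absent from its matrix are
#' skipped with a warning.
#'
#' @param candidates Candidate predictions from [candidatePairs()].
#' @param mirnaSE,geneSE Annotated expression matrices; their sample
#'   intersection (>= 4 samples) is used.
#' @param alpha Strict threshold on the adjusted p-value; default 0.005.
#' @return data.frame of regulatory pairs: \code{mirna_id},
#'   \code{gene_symbol}, \code{mirsvr_score}, \code{pair_rho},
#'   \code{pair_adj_p}, ordered as in \code{candidates}.
#' @export
pairAnticorrelation <- function(candidates, mirnaSE, geneSE, alpha = 0.005) {
    shared <- intersect(colnames(mirnaSE), colnames(geneSE))
    if (length(shared) < 4L)
        stop("need at least 4 shared samples between the platforms",
             call. = FALSE)
    mv <- assay(mirnaSE, "exprs")[, shared, drop = FALSE]
    gv <- assay(geneSE, "exprs")[, shared, drop = FALSE]
    ok <- candidates$mirna_id %in% rownames(mv) &
        candidates$gene_symbol %in% rownames(gv)
    if (any(!ok))
        warning(sum(!ok), " candidate pair(s) reference features absent ",
                "from the matrices; skipped", call. = FALSE)
    cand <- candidates[ok, , drop = FALSE]
    if (!nrow(cand))
        return(data.frame(mirna_id = character(), gene_symbol = character(),
                          mirsvr_score = numeric(), pair_rho = numeric(),
                          pair_adj_p = numeric()))
    rho <- numeric(nrow(cand))
    p <- rep(1, nrow(cand))
    usable <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
        x <- mv[cand$mirna_id[i], ]
        y <- gv[cand$gene_symbol[i], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
            usable[i] <- FALSE
            next
        }
        st <- spearmanRho(x, y)
        rho[i] <- st$rho
        p[i] <- st$p_value
    }
    if (any(!usable))
        warning(sum(!usable), " candidate pair(s) with constant expression",
                " skipped", call. = FALSE)
    adj <- bhAdjust(p)
    keep <- usable & rho < 0 & adj < alpha
    out <- data.frame(
        mirna_id = cand$mirna_id[keep],
        gene_symbol = cand$gene_symbol[keep],
        mirsvr_score = cand$mirsvr_score[keep],
        pair_rho = rho[keep],
        pair_adj_p = adj[keep])
    rownames(out) <- NULL
    out
}

#' Derive the unique miRNA and gene signatures from regulatory pairs
#'
#' The miRNA signature collects the unique miRNAs of the pair list, the
#' gene signature the unique target genes, each ordered by first appearance
#' and annotated with its severity-correlation rho from the corresponding
#' screen (not the pair correlation) — the severity sign is the score
#' weight.
#'
#' @param pairs Regulatory-pair data.frame ([pairAnticorrelation()] output
#'   or the packaged pair fixture).
#' @param mirnaScreen,geneScreen Screen records (or any data.frame with
#'   \code{feature_id} and \code{rho}) covering every pair member.
#' @return List with [Signature-class] elements \code{mirna} and
#'   \code{gene}.
#' @examples
#' msig <- sarcoidosisFixture("mirna_signature")
#' gsig <- sarcoidosisFixture("gene_signature")
#' sigs <- deriveSignatures(
#'     sarcoidosisFixture("pairs"),
#'     data.frame(feature_id = featureIds(msig), rho = featureRho(msig)),
#'     data.frame(feature_id = featureIds(gsig), rho = featureRho(gsig)))
#' length(sigs$mirna); length(sigs$gene)
#' @export
deriveSignatures <- function(pairs, mirnaScreen, geneScreen) {
    if (!nrow(pairs))
        stop("empty pair list: cannot derive signatures", call. = FALSE)
    um <- unique(pairs$mirna_id)
    ug <- unique(pairs$gene_symbol)
    mm <- match(um, mirnaScreen$feature_id)
    gm <- match(ug, geneScreen$feature_id)
    if (anyNA(mm))
        stop("no miRNA screen record for: ",
             paste(um[is.na(mm)], collapse = ", "), call. = FALSE)
    if (anyNA(gm))
        stop("no gene screen record for: ",
             paste(ug[is.na(gm)], collapse = ", "), call. = FALSE)
    list(
        mirna = Signature(sprintf("%d-miRNA signature", length(um)),
                          "miRNA", um, mirnaScreen$rho[mm]),
        gene = Signature(sprintf("%d-gene signature", length(ug)),
                         "mRNA", ug, geneScreen$rho[gm]))
}
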