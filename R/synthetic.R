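# Synthetic cohorts with the statistical structure the pipeline assumes:
# three ordered severity groups, miRNAs with a planted monotone severity
# trend, target genes generated conditionally on their miRNA's realized
# expression (hence negatively coupled), and pure-noise decoys.  All
# expression is Gaussian on the log scale.

.group_labels <- function(nHC, nUS, nCS) {
    c(sprintf("HC%02d", seq_len(nHC)),
      sprintf("US%02d", seq_len(nUS)),
      sprintf("CS%02d", seq_len(nCS)))
}

.make_se <- function(vals, platform, annotation, detected = NULL) {
    if (is.null(detected))
        detected <- matrix(TRUE, nrow(vals), ncol(vals),
                           dimnames = dimnames(vals))
    se <- SummarizedExperiment(assays = list(exprs = vals,
                                             detected = detected))
    S4Vectors::metadata(se)$platform <- platform
    attachAnnotation(se, annotation)
}

#' Generate a synthetic three-group discovery cohort
#'
#' Produces paired miRNA and mRNA expression matrices over overlapping
#' sample sets, a detection mask, and the planted ground truth.  A signal
#' miRNA i follows \code{baseline + direction_i * severityEffect * severity
#' + N(0, noiseSd)}; each planted target gene follows \code{baseline -
#' couplingStrength * (its miRNA's expression) + N(0, noiseSd)}, so planted
#' pairs are negatively correlated and target genes inherit a severity
#' trend of opposite sign.  \code{nDirectGenes} additional genes carry a
#' direct severity trend of random direction with no miRNA coupling — the
#' analogue of severity-associated genes outside the regulatory pairs,
#' which populate the disease-related resampling pool.  All remaining
#' features are baseline plus noise.
#' Mirroring the emulated study design, one signal miRNA is planted
#' downward and the rest upward.  Generation is deterministic given
#' \code{spec@seed}.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A list with elements \code{mirna} and \code{gene}
#'   (SummarizedExperiments with assays \code{exprs}, \code{detected} and
#'   annotated colData), \code{annotation} (the union annotation) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' d <- generateDiscovery(syntheticSpec(nGeneFeatures = 200, seed = 3))
#' dim(d$mirna); dim(d$gene)
#' @export
generateDiscovery <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    nCSmax <- max(spec@nCSmirna, spec@nCSgene)
    all_ids <- .group_labels(spec@nHC, spec@nUS, nCSmax)
    all_grp <- rep(c("HC", "US", "CS"),
                   c(spec@nHC, spec@nUS, nCSmax))
    sev <- .severity_code(all_grp)
    mirna_ids <- sprintf("miR-%03d", seq_len(spec@nMirnaFeatures))
    gene_ids <- sprintf("GENE%04d", seq_len(spec@nGeneFeatures))
    n_all <- length(all_ids)
    withr::with_seed(spec@seed, {
        # draw order: signal sets, directions, baselines, miRNA noise,
        # gene noise, detection mask
        signal_mirnas <- sort(sample(mirna_ids, spec@nSignalMirnas))
        n_tg <- spec@nSignalMirnas * spec@targetsPerMirna
        signal_genes <- sort(sample(gene_ids, n_tg))
        target_of <- split(signal_genes,
                           rep(signal_mirnas, each = spec@targetsPerMirna))
        direct_genes <- sort(sample(setdiff(gene_ids, signal_genes),
                                    spec@nDirectGenes))
        dir_d <- stats::setNames(
            sample(c(-1, 1), spec@nDirectGenes, replace = TRUE),
            direct_genes)
        dir_m <- stats::setNames(
            rep(1, spec@nSignalMirnas), signal_mirnas)
        dir_m[[spec@nSignalMirnas]] <- -1  # one down-regulated miRNA
        base_m <- stats::setNames(stats::rnorm(spec@nMirnaFeatures, 8, 1),
                                  mirna_ids)
        base_g <- stats::setNames(stats::rnorm(spec@nGeneFeatures, 8, 1),
                                  gene_ids)
        mirna_all <- matrix(
            stats::rnorm(spec@nMirnaFeatures * n_all, 0, spec@noiseSd),
            spec@nMirnaFeatures, n_all,
            dimnames = list(mirna_ids, all_ids))
        mirna_all <- mirna_all + base_m
        for (m in signal_mirnas)
            mirna_all[m, ] <- mirna_all[m, ] +
                dir_m[[m]] * spec@severityEffect * spec@noiseSd * sev
        gene_vals <- matrix(
            stats::rnorm(spec@nGeneFeatures * n_all, 0, spec@noiseSd),
            spec@nGeneFeatures, n_all,
            dimnames = list(gene_ids, all_ids))
        gene_vals <- gene_vals + base_g
        for (m in signal_mirnas)
            for (g in target_of[[m]])
                gene_vals[g, ] <- gene_vals[g, ] -
                    spec@couplingStrength * (mirna_all[m, ] - base_m[[m]])
        for (g in direct_genes)
            gene_vals[g, ] <- gene_vals[g, ] +
                dir_d[[g]] * spec@severityEffect * spec@noiseSd * sev
        det_m <- matrix(TRUE, spec@nMirnaFeatures, n_all,
                        dimnames = list(mirna_ids, all_ids))
        det_g <- matrix(TRUE, spec@nGeneFeatures, n_all,
                        dimnames = list(gene_ids, all_ids))
        if (spec@detectionDropout > 0) {
            det_m[] <- stats::runif(length(det_m)) >= spec@detectionDropout
            det_g[] <- stats::runif(length(det_g)) >= spec@detectionDropout
        }
    })
    annotation <- makeAnnotation(all_ids, all_grp)
    keep_m <- c(seq_len(spec@nHC + spec@nUS),
                spec@nHC + spec@nUS + seq_len(spec@nCSmirna))
    keep_g <- c(seq_len(spec@nHC + spec@nUS),
                spec@nHC + spec@nUS + seq_len(spec@nCSgene))
    gene_dir <- stats::setNames(
        rep(-unlist(dir_m)[rep(signal_mirnas,
                               each = spec@targetsPerMirna)], 1),
        unlist(target_of[signal_mirnas]))
    truth <- new("GroundTruth",
        signalMirnas = signal_mirnas,
        mirnaDirection = dir_m,
        plantedPairs = data.frame(
            mirna_id = rep(signal_mirnas, each = spec@targetsPerMirna),
            gene_symbol = unlist(target_of[signal_mirnas],
                                 use.names = FALSE)),
        signalGenes = signal_genes,
        geneDirection = gene_dir,
        directGenes = direct_genes,
        directDirection = dir_d,
        mirnaUniverse = mirna_ids,
        geneUniverse = gene_ids)
    validObject(truth)
    list(
        mirna = .make_se(mirna_all[, keep_m, drop = FALSE], "miRNA",
                         annotation, det_m[, keep_m, drop = FALSE]),
        gene = .make_se(gene_vals[, keep_g, drop = FALSE], "mRNA",
                        annotation, det_g[, keep_g, drop = FALSE]),
        annotation = annotation,
        truth = truth)
}

#' Generate a target-prediction table matched to a synthetic cohort
#'
#' Every planted regulatory pair receives a mirSVR-like score drawn
#' uniformly in [-2.0, -1.2] (passing the -1.2 cutoff by construction);
#' decoy predictions are random non-planted miRNA-gene pairs with scores in
#' (-1.2, -0.1).  Deterministic given \code{spec@seed}.
#'
#' @param truth [GroundTruth-class] from [generateDiscovery()].
#' @param spec The same [SyntheticSpec-class] that generated \code{truth}.
#' @return A target-prediction data.frame (\code{mirna_id},
#'   \code{gene_symbol}, \code{mirsvr_score}, logical \code{planted}).
#' @export
generateTargetTable <- function(truth, spec) {
    stopifnot(is(truth, "GroundTruth"), is(spec, "SyntheticSpec"))
    pp <- truth@plantedPairs
    n_p <- nrow(pp)
    planted_key <- paste(pp$mirna_id, pp$gene_symbol)
    withr::with_seed(spec@seed + 1L, {
        score_p <- stats::runif(n_p, -2.0, -1.2)
        n_d <- spec@nDecoyPredictions
        decoys <- data.frame(mirna_id = character(), gene_symbol = character())
        if (n_d > 0L) {
            got <- 0L
            acc <- list()
            while (got < n_d) {
                cand <- data.frame(
                    mirna_id = sample(truth@mirnaUniverse, n_d, replace = TRUE),
                    gene_symbol = sample(truth@geneUniverse, n_d,
                                         replace = TRUE))
                key <- paste(cand$mirna_id, cand$gene_symbol)
                cand <- cand[!key %in% planted_key & !duplicated(key), ,
                             drop = FALSE]
                acc[[length(acc) + 1L]] <- cand
                got <- sum(vapply(acc, nrow, integer(1L)))
            }
            decoys <- do.call(rbind, acc)
            key <- paste(decoys$mirna_id, decoys$gene_symbol)
            decoys <- decoys[!duplicated(key), , drop = FALSE][seq_len(n_d), ]
        }
        score_d <- stats::runif(nrow(decoys), -1.2, -0.1)
    })
    out <- rbind(
        data.frame(mirna_id = pp$mirna_id, gene_symbol = pp$gene_symbol,
                   mirsvr_score = score_p, planted = TRUE),
        data.frame(mirna_id = decoys$mirna_id,
                   gene_symbol = decoys$gene_symbol,
                   mirsvr_score = score_d,
                   planted = rep(FALSE, nrow(decoys))))
    rownames(out) <- NULL
    out
}

#' Generate a synthetic binary validation cohort
#'
#' Case samples are shifted by \code{sgn(rho_i) * shift} on every signature
#' feature (so cases score higher under the sign-weighted score);
#' background features are pure noise.  Deterministic given \code{seed}.
#'
#' @param signature A [Signature-class].
#' @param nControls,nCases Group sizes.
#' @param shift Per-feature case shift on the expression scale.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param nFeatures Total number of features in the matrix (signature
#'   features plus pure-noise background); at least the signature size.
#'   Ignored when \code{backgroundIds} is given.
#' @param backgroundIds Optional character ids for the background
#'   features, e.g. the discovery platform's gene universe, so that
#'   features outside the signature are measured under the same names in
#'   validation — required for resampling pools drawn from the discovery
#'   screen.  Defaults to anonymous \code{BG....} ids.
#' @return A SummarizedExperiment with assay \code{exprs} and colData
#'   \code{group} (\code{control}/\code{case}) and \code{severity} (0/1).
#' @examples
#' sig <- sarcoidosisFixture("gene_signature")
#' v <- generateValidation(sig, 8, 8, shift = 2, seed = 1)
#' table(SummarizedExperiment::colData(v)$group)
#' @export
generateValidation <- function(signature, nControls, nCases, shift = 2,
                               noiseSd = 1, seed = 1L, nFeatures = 500L,
                               backgroundIds = NULL) {
    stopifnot(is(signature, "Signature"), nControls >= 1L, nCases >= 1L)
    sig_ids <- featureIds(signature)
    if (is.null(backgroundIds)) {
        nFeatures <- max(as.integer(nFeatures), length(sig_ids))
        backgroundIds <- sprintf("BG%04d",
                                 seq_len(nFeatures - length(sig_ids)))
    } else {
        backgroundIds <- setdiff(backgroundIds, sig_ids)
    }
    feat <- c(sig_ids, backgroundIds)
    sids <- c(sprintf("ctrl%02d", seq_len(nControls)),
              sprintf("case%02d", seq_len(nCases)))
    grp <- rep(c("control", "case"), c(nControls, nCases))
    n <- length(sids)
    withr::with_seed(as.integer(seed), {
        base <- stats::rnorm(length(feat), 8, 1)
        vals <- matrix(stats::rnorm(length(feat) * n, 0, noiseSd),
                       length(feat), n, dimnames = list(feat, sids)) + base
    })
    case_idx <- which(grp == "case")
    w <- sign(featureRho(signature))
    vals[sig_ids, case_idx] <- vals[sig_ids, case_idx] + w * shift
    .make_se(vals, signature@platform, makeAnnotation(sids, grp))
}
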