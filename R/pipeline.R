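# End-to-end orchestration: simulate -> screen -> integrate -> score ->
# evaluate -> resample, with every intermediate artifact written as TSV,
# a deterministic run manifest, and a plain-text log.

#' Pipeline configuration
#'
#' Collects thresholds, cohort sources and run parameters.  All threshold
#' defaults are the conventional published values: miRNA screen adjusted
#' P < 0.05, gene screen adjusted P < 0.0005, pair anti-correlation
#' adjusted P < 0.005, mirSVR cutoff -1.2, presence fraction 2/3, 1,000
#' resamples.
#'
#' @param synthetic A [SyntheticSpec-class] for synthetic mode, or
#'   \code{NULL} to read files.
#' @param mirna_matrix,gene_matrix,annotation,target_table File paths
#'   (TSV) used when \code{synthetic} is \code{NULL}.
#' @param validation_cohorts For file mode, a list of
#'   \code{list(matrix =, annotation =)} path pairs; ignored in synthetic
#'   mode, where two validation cohorts (20/40 and 25/12
#'   controls/cases) are generated from the derived gene signature.
#' @param mirna_alpha,gene_alpha,pair_alpha Strict adjusted-p thresholds.
#' @param mirsvr_cutoff Inclusive mirSVR score cutoff.
#' @param presence_fraction Presence-filter fraction.
#' @param validation_shift,validation_noise_sd,validation_n_features
#'   Synthetic validation-cohort parameters.
#' @param n_resamples Resampling-test draws.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(synthetic = syntheticSpec(),
                           mirna_matrix = NULL, gene_matrix = NULL,
                           annotation = NULL, target_table = NULL,
                           validation_cohorts = NULL,
                           mirna_alpha = 0.05, gene_alpha = 5e-4,
                           pair_alpha = 0.005, mirsvr_cutoff = -1.2,
                           presence_fraction = 2 / 3,
                           validation_shift = 2,
                           validation_noise_sd = 1,
                           validation_n_features = 500L,
                           n_resamples = 1000L, seed = 1L) {
    stopifnot(mirna_alpha > 0, mirna_alpha <= 1,
              gene_alpha > 0, gene_alpha <= 1,
              pair_alpha > 0, pair_alpha <= 1,
              presence_fraction > 0, presence_fraction <= 1,
              n_resamples >= 1L)
    if (!is.null(synthetic)) {
        synthetic@seed <- as.integer(seed)
        validObject(synthetic)
    }
    structure(list(
        synthetic = synthetic,
        mirna_matrix = mirna_matrix, gene_matrix = gene_matrix,
        annotation = annotation, target_table = target_table,
        validation_cohorts = validation_cohorts,
        mirna_alpha = mirna_alpha, gene_alpha = gene_alpha,
        pair_alpha = pair_alpha, mirsvr_cutoff = mirsvr_cutoff,
        presence_fraction = presence_fraction,
        validation_shift = validation_shift,
        validation_noise_sd = validation_noise_sd,
        validation_n_features = as.integer(validation_n_features),
        n_resamples = as.integer(n_resamples),
        seed = as.integer(seed)), class = "pipelineConfig")
}

.config_echo <- function(config) {
    out <- unclass(config)
    out$validation_cohorts <- NULL
    if (!is.null(out$synthetic)) {
        sp <- out$synthetic
        out$synthetic <- lapply(stats::setNames(slotNames(sp),
                                                slotNames(sp)),
                                function(s) slot(sp, s))
    }
    out
}

#' Run the full discovery-to-resampling pipeline
#'
#' Executes six stages — simulate (or load), screen, integrate, score,
#' evaluate, resample — writing every intermediate artifact as TSV into
#' \code{outdir}, plus \code{manifest.json} (stages, outputs, counts, seed
#' and config echo; deliberately free of timestamps so reruns with the
#' same config are bitwise-identical) and \code{run.log}.  Any stage
#' failure aborts with the stage name in the error.
#'
#' @param config A [pipelineConfig()] list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- c(
        sprintf("sarcoSig pipeline, package version %s",
                as.character(utils::packageVersion("sarcoSig"))),
        sprintf("seed: %d", config$seed))
    manifest <- list(
        package = "sarcoSig",
        version = as.character(utils::packageVersion("sarcoSig")),
        seed = config$seed,
        config = .config_echo(config),
        stages = list())
    say <- function(...) log_lines <<- c(log_lines, sprintf(...))
    stage <- function(name, body) {
        res <- tryCatch(body(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        manifest$stages[[length(manifest$stages) + 1L]] <<-
            c(list(name = name), res)
        res
    }

    # -- stage 1: simulate (or load inputs) -------------------------------
    env <- new.env()
    stage("simulate", function() {
        if (!is.null(config$synthetic)) {
            d <- generateDiscovery(config$synthetic)
            env$mirna <- d$mirna
            env$gene <- d$gene
            env$truth <- d$truth
            env$targets <- generateTargetTable(d$truth, config$synthetic)
            say("simulate: %d miRNA features x %d samples; %d gene features x %d samples",
                nrow(d$mirna), ncol(d$mirna), nrow(d$gene), ncol(d$gene))
        } else {
            ann <- readAnnotation(config$annotation)
            env$mirna <- attachAnnotation(
                readExpressionMatrix(config$mirna_matrix, "miRNA"), ann)
            env$gene <- attachAnnotation(
                readExpressionMatrix(config$gene_matrix, "mRNA"), ann)
            env$targets <- readTargetTable(config$target_table)
            env$truth <- NULL
            say("load: %d miRNA features, %d gene features",
                nrow(env$mirna), nrow(env$gene))
        }
        writeExpressionMatrix(env$mirna, file.path(outdir, "mirna_matrix.tsv"))
        writeExpressionMatrix(env$gene, file.path(outdir, "gene_matrix.tsv"))
        writeTsv(as.data.frame(colData(env$gene)),
                 file.path(outdir, "annotation.tsv"))
        writeTsv(env$targets[, c("mirna_id", "gene_symbol", "mirsvr_score")],
                 file.path(outdir, "target_predictions.tsv"))
        list(outputs = c("mirna_matrix.tsv", "gene_matrix.tsv",
                         "annotation.tsv", "target_predictions.tsv"),
             n_mirna_features = nrow(env$mirna),
             n_gene_features = nrow(env$gene),
             n_predictions = nrow(env$targets))
    })

    # -- stage 2: screen ---------------------------------------------------
    stage("screen", function() {
        env$mirna_f <- presenceFilter(env$mirna,
                                      fraction = config$presence_fraction)
        env$gene_f <- presenceFilter(env$gene,
                                     fraction = config$presence_fraction)
        env$mirna_screen <- suppressWarnings(
            screenFeatures(env$mirna_f, alpha = config$mirna_alpha))
        env$gene_screen <- suppressWarnings(
            screenFeatures(env$gene_f, alpha = config$gene_alpha))
        writeTsv(env$mirna_screen, file.path(outdir, "screen_mirna.tsv"))
        writeTsv(env$gene_screen, file.path(outdir, "screen_gene.tsv"))
        say("screen: %d DE miRNAs (adj P < %g), %d DE genes (adj P < %g)",
            nrow(env$mirna_screen), config$mirna_alpha,
            nrow(env$gene_screen), config$gene_alpha)
        list(outputs = c("screen_mirna.tsv", "screen_gene.tsv"),
             n_de_mirnas = nrow(env$mirna_screen),
             n_de_genes = nrow(env$gene_screen))
    })

    # -- stage 3: integrate ------------------------------------------------
    stage("integrate", function() {
        filt <- filterPredictions(env$targets, cutoff = config$mirsvr_cutoff)
        cand <- candidatePairs(filt, env$mirna_screen, env$gene_screen)
        env$pairs <- suppressWarnings(pairAnticorrelation(
            cand, env$mirna_f, env$gene_f, alpha = config$pair_alpha))
        sigs <- deriveSignatures(env$pairs, env$mirna_screen,
                                 env$gene_screen)
        env$mirna_sig <- sigs$mirna
        env$gene_sig <- sigs$gene
        writeTsv(env$pairs, file.path(outdir, "pairs.tsv"))
        writeTsv(data.frame(feature_id = featureIds(sigs$mirna),
                            rho = sigs$mirna@rho),
                 file.path(outdir, "signature_mirna.tsv"))
        writeTsv(data.frame(feature_id = featureIds(sigs$gene),
                            rho = sigs$gene@rho),
                 file.path(outdir, "signature_gene.tsv"))
        say("integrate: %d predictions pass mirSVR <= %g, %d candidates, %d pairs, %d + %d signature features",
            nrow(filt), config$mirsvr_cutoff, nrow(cand), nrow(env$pairs),
            length(sigs$mirna), length(sigs$gene))
        list(outputs = c("pairs.tsv", "signature_mirna.tsv",
                         "signature_gene.tsv"),
             n_filtered_predictions = nrow(filt),
             n_candidate_pairs = nrow(cand),
             n_pairs = nrow(env$pairs),
             n_signature_mirnas = length(sigs$mirna),
             n_signature_genes = length(sigs$gene))
    })

    # -- stage 4: score ----------------------------------------------------
    stage("score", function() {
        env$mirna_score <- scoreCohort(env$mirna_f, env$mirna_sig)
        env$gene_score <- scoreCohort(env$gene_f, env$gene_sig)
        writeTsv(data.frame(sample_id = names(sampleScores(env$mirna_score)),
                            score = sampleScores(env$mirna_score)),
                 file.path(outdir, "scores_mirna.tsv"))
        writeTsv(data.frame(sample_id = names(sampleScores(env$gene_score)),
                            score = sampleScores(env$gene_score)),
                 file.path(outdir, "scores_gene.tsv"))
        say("score: coverage %.2f (miRNA) / %.2f (gene)",
            scoreCoverage(env$mirna_score), scoreCoverage(env$gene_score))
        list(outputs = c("scores_mirna.tsv", "scores_gene.tsv"),
             mirna_coverage = scoreCoverage(env$mirna_score),
             gene_coverage = scoreCoverage(env$gene_score))
    })

    # -- stage 5: evaluate -------------------------------------------------
    stage("evaluate", function() {
        tr_m <- severityTrend(env$mirna_score, colData(env$mirna_f))
        tr_g <- severityTrend(env$gene_score, colData(env$gene_f))
        env$validation <- if (!is.null(config$synthetic)) {
            # validation cohorts measure the discovery gene universe, so
            # resampling pools drawn from the screen remain scorable
            list(
                generateValidation(env$gene_sig, 20, 40,
                    shift = config$validation_shift,
                    noiseSd = config$validation_noise_sd,
                    seed = config$seed + 11L,
                    backgroundIds = rownames(env$gene_f)),
                generateValidation(env$gene_sig, 25, 12,
                    shift = config$validation_shift,
                    noiseSd = config$validation_noise_sd,
                    seed = config$seed + 12L,
                    backgroundIds = rownames(env$gene_f)))
        } else if (!is.null(config$validation_cohorts)) {
            lapply(config$validation_cohorts, function(vc)
                attachAnnotation(
                    readExpressionMatrix(vc$matrix, "mRNA"),
                    readAnnotation(vc$annotation)))
        } else list()
        rows <- data.frame(cohort = "discovery", metric = "trend_rho",
                           value = c(tr_m$rho, tr_g$rho),
                           signature = c(signatureName(env$mirna_sig),
                                         signatureName(env$gene_sig)))
        for (i in seq_along(env$validation)) {
            se <- env$validation[[i]]
            sc <- suppressWarnings(scoreCohort(se, env$gene_sig))
            lab <- colData(se)$severity
            roc <- rocAuc(sc, lab)
            tt <- groupTtest(sc, lab)
            rows <- rbind(rows, data.frame(
                cohort = sprintf("validation%d", i),
                metric = c("auc", "t", "p_ttest"),
                value = c(roc$auc, tt$t, tt$p),
                signature = signatureName(env$gene_sig)))
        }
        writeTsv(rows, file.path(outdir, "evaluation.tsv"))
        say("evaluate: discovery trend rho %.3f (miRNA) / %.3f (gene); %d validation cohort(s)",
            tr_m$rho, tr_g$rho, length(env$validation))
        list(outputs = "evaluation.tsv",
             trend_rho_mirna = tr_m$rho, trend_rho_gene = tr_g$rho,
             n_validation_cohorts = length(env$validation))
    })

    # -- stage 6: resample -------------------------------------------------
    stage("resample", function() {
        if (!length(env$validation)) {
            say("resample: skipped (no validation cohorts)")
            return(list(outputs = character(), skipped = TRUE))
        }
        res_g <- runResamplingTest(env$gene_sig, env$validation,
                                   pool = "genome",
                                   nResamples = config$n_resamples,
                                   seed = config$seed + 21L)
        res_d <- runResamplingTest(env$gene_sig, env$validation,
                                   pool = "disease_related",
                                   screen = env$gene_screen,
                                   nResamples = config$n_resamples,
                                   seed = config$seed + 22L)
        writeTsv(data.frame(pool = c("genome", "disease_related"),
                            observed = c(observedStat(res_g),
                                         observedStat(res_d)),
                            p_right = c(pRight(res_g), pRight(res_d)),
                            n_resamples = config$n_resamples),
                 file.path(outdir, "resampling_summary.tsv"))
        writeTsv(data.frame(pool = rep(c("genome", "disease_related"),
                                       each = config$n_resamples),
                            auc_sum = c(nullDraws(res_g),
                                        nullDraws(res_d))),
                 file.path(outdir, "resampling_null.tsv"))
        say("resample: observed %.3f, P=%.4g (genome) / observed %.3f, P=%.4g (disease pool)",
            observedStat(res_g), pRight(res_g),
            observedStat(res_d), pRight(res_d))
        list(outputs = c("resampling_summary.tsv", "resampling_null.tsv"),
             observed_auc_sum = observedStat(res_g),
             p_right_genome = pRight(res_g),
             p_right_disease = pRight(res_d))
    })

    writeLines(log_lines, file.path(outdir, "run.log"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}
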