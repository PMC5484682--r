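# Small in-code builders used across test files.

library(SummarizedExperiment)

make_se <- function(vals, group = NULL, platform = "mRNA") {
    se <- SummarizedExperiment(assays = list(exprs = vals))
    S4Vectors::metadata(se)$platform <- platform
    if (!is.null(group))
        se <- attachAnnotation(se, makeAnnotation(colnames(vals), group))
    se
}

write_tmp_tsv <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

# A tiny fully-recoverable synthetic design for fast end-to-end tests.
small_spec <- function(seed = 1L, nDecoyPredictions = 30L, ...) {
    syntheticSpec(nMirnaFeatures = 40L, nGeneFeatures = 120L,
                  nSignalMirnas = 4L, targetsPerMirna = 2L,
                  nDirectGenes = 20L,
                  nDecoyPredictions = nDecoyPredictions, seed = seed, ...)
}
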