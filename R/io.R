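# Readers and writers for the plain TSV dialect used throughout: tab
# separated, UTF-8, "." decimal, no quoting.  Unicode minus signs (U+2212)
# are normalized to ASCII hyphen-minus on read so values copied from
# typeset tables parse cleanly.

.read_tsv_lines <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    gsub("−", "-", lines)
}

.parse_numeric <- function(x, what, rows, cols) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad)) {
        i <- bad[[1L]]
        stop(sprintf(
            "%s: non-numeric value '%s' at row %d, column '%s'",
            what, x[[i]], rows[[i]], cols[[i]]), call. = FALSE)
    }
    out
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (miRNA names or gene symbols); the body must be numeric log-scale
#' expression.  Rows sharing a feature id (multiple probes mapping to one
#' symbol) are collapsed to their arithmetic mean.
#'
#' @param path Path to the TSV file.
#' @param platform \code{"miRNA"} or \code{"mRNA"}; stored in the object
#'   metadata.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{exprs} (features x samples), feature ids as rownames, sample ids
#'   as colnames and \code{metadata(x)$platform} set.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "STAT4\t1\t2", "CBLB\t3\t4"), tf)
#' se <- readExpressionMatrix(tf, "mRNA")
#' dim(se)
#' @export
readExpressionMatrix <- function(path, platform = c("miRNA", "mRNA")) {
    platform <- match.arg(platform)
    lines <- .read_tsv_lines(path)
    if (length(lines) < 2L)
        stop("expression TSV must have a header row and at least one feature",
             call. = FALSE)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L)
        stop("malformed header: need a feature-id column and >= 1 sample",
             call. = FALSE)
    sample_ids <- header[-1L]
    if (anyDuplicated(sample_ids))
        stop("duplicate sample ids in header", call. = FALSE)
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nc <- lengths(body)
    if (any(nc != length(header)))
        stop(sprintf("row %d has %d fields, expected %d",
                     which(nc != length(header))[[1L]] + 1L,
                     nc[nc != length(header)][[1L]], length(header)),
             call. = FALSE)
    feat <- vapply(body, `[[`, character(1L), 1L)
    cells <- do.call(rbind, lapply(body, `[`, -1L))
    rows <- rep(seq_along(feat) + 1L, times = ncol(cells))
    cols <- rep(sample_ids, each = nrow(cells))
    vals <- matrix(.parse_numeric(as.vector(cells), "expression matrix",
                                  rows, cols),
                   nrow = length(feat))
    if (!all(is.finite(vals)))
        stop(sprintf("expression matrix: non-finite value at row %d",
                     which(!apply(is.finite(vals), 1L, all))[[1L]] + 1L),
             call. = FALSE)
    if (anyDuplicated(feat)) {
        vals <- rowsum(vals, group = feat, reorder = FALSE) /
            as.vector(table(factor(feat, levels = unique(feat))))
        feat <- unique(feat)
    }
    dimnames(vals) <- list(feat, sample_ids)
    se <- SummarizedExperiment(assays = list(exprs = vals))
    S4Vectors::metadata(se)$platform <- platform
    se
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]: full-precision values (17
#' significant digits) so a write/read round trip is loss-free.
#'
#' @param se A SummarizedExperiment with an \code{exprs} assay.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(se, path) {
    vals <- assay(se, "exprs")
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
        paste(c("feature_id", colnames(vals)), collapse = "\t"),
        vapply(seq_len(nrow(vals)), function(i) {
            paste(c(rownames(vals)[i],
                    formatC(vals[i, ], format = "g", digits = 17)),
                  collapse = "\t")
        }, character(1L))), con)
    invisible(path)
}

.severity_code <- function(group) {
    unknown <- setdiff(unique(group), names(GROUP_CODES))
    if (length(unknown))
        stop("unknown group label(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    unname(GROUP_CODES[group])
}

#' Read a cohort annotation from TSV
#'
#' Expects columns \code{sample_id} and \code{group}.  Group labels are
#' either the ordinal severity strata \code{HC}/\code{US}/\code{CS}
#' (healthy control, uncomplicated, complicated; coded 0/1/2) or the binary
#' labels \code{control}/\code{case} (coded 0/1).
#'
#' @param path Path to the TSV file.
#' @return An [S4Vectors::DataFrame] with columns \code{sample_id},
#'   \code{group} and integer \code{severity}, rownames = sample ids.
#' @export
readAnnotation <- function(path) {
    lines <- .read_tsv_lines(path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    need <- c("sample_id", "group")
    if (!all(need %in% header))
        stop("annotation TSV needs columns sample_id and group",
             call. = FALSE)
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    sid <- vapply(body, `[[`, character(1L), match("sample_id", header))
    grp <- vapply(body, `[[`, character(1L), match("group", header))
    if (anyDuplicated(sid))
        stop("duplicate sample id: ", sid[duplicated(sid)][[1L]],
             call. = FALSE)
    makeAnnotation(sid, grp)
}

#' Build a cohort annotation in memory
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param group Group label per sample (\code{HC}/\code{US}/\code{CS} or
#'   \code{control}/\code{case}).
#' @return An [S4Vectors::DataFrame] as in [readAnnotation()].
#' @examples
#' makeAnnotation(c("s1", "s2", "s3"), c("HC", "US", "CS"))$severity
#' @export
makeAnnotation <- function(sample_ids, group) {
    sample_ids <- as.character(sample_ids)
    group <- as.character(group)
    if (anyDuplicated(sample_ids))
        stop("duplicate sample ids", call. = FALSE)
    if (length(group) != length(sample_ids))
        stop("every sample needs exactly one group label", call. = FALSE)
    sev <- .severity_code(group)
    if (length(unique(group)) < 2L)
        stop("annotation must contain at least two distinct groups",
             call. = FALSE)
    DataFrame(sample_id = sample_ids, group = group, severity = sev,
              row.names = sample_ids)
}

#' Attach a cohort annotation to an expression matrix
#'
#' Subsets and orders the annotation to the matrix's samples and installs
#' it as \code{colData}; every matrix sample must be annotated.
#'
#' @param se SummarizedExperiment from [readExpressionMatrix()].
#' @param annotation DataFrame from [readAnnotation()]/[makeAnnotation()].
#' @return \code{se} with \code{colData} columns \code{sample_id},
#'   \code{group}, \code{severity}.
#' @export
attachAnnotation <- function(se, annotation) {
    missing <- setdiff(colnames(se), annotation$sample_id)
    if (length(missing))
        stop("samples without annotation: ",
             paste(missing, collapse = ", "), call. = FALSE)
    colData(se)[, c("sample_id", "group", "severity")] <-
        annotation[colnames(se), c("sample_id", "group", "severity")]
    se
}

#' Read a miRNA target-prediction table from TSV
#'
#' Expects columns \code{mirna_id}, \code{gene_symbol},
#' \code{mirsvr_score}.  Duplicate (miRNA, gene) rows are collapsed keeping
#' the most negative mirSVR score — the strongest predicted binding and the
#' conservative choice for a \code{<= cutoff} filter.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per unique predicted pair.
#' @export
readTargetTable <- function(path) {
    lines <- .read_tsv_lines(path)
    if (!length(lines) || (length(lines) == 1L && !nzchar(lines)))
        return(data.frame(mirna_id = character(), gene_symbol = character(),
                          mirsvr_score = numeric()))
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    need <- c("mirna_id", "gene_symbol", "mirsvr_score")
    if (!all(need %in% header))
        stop("target table needs columns mirna_id, gene_symbol, mirsvr_score",
             call. = FALSE)
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    if (!length(body))
        return(data.frame(mirna_id = character(), gene_symbol = character(),
                          mirsvr_score = numeric()))
    df <- data.frame(
        mirna_id = vapply(body, `[[`, character(1L),
                          match("mirna_id", header)),
        gene_symbol = vapply(body, `[[`, character(1L),
                             match("gene_symbol", header)),
        mirsvr_score = .parse_numeric(
            vapply(body, `[[`, character(1L), match("mirsvr_score", header)),
            "target table", seq_along(body) + 1L,
            rep("mirsvr_score", length(body))))
    collapseTargetTable(df)
}

#' @rdname readTargetTable
#' @param predictions A target-prediction data.frame.
#' @export
collapseTargetTable <- function(predictions) {
    key <- paste(predictions$mirna_id, predictions$gene_symbol, sep = "\r")
    if (anyDuplicated(key)) {
        ord <- order(match(key, unique(key)), predictions$mirsvr_score)
        predictions <- predictions[ord, , drop = FALSE]
        predictions <- predictions[!duplicated(key[ord]), , drop = FALSE]
        rownames(predictions) <- NULL
    }
    predictions
}

#' Write a generic data.frame in the package TSV dialect
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Packaged sarcoidosis signature fixtures
#'
#' Published reference results shipped with the package: the 19
#' severity-associated miRNA/target-gene regulatory pairs with mirSVR
#' scores and pair correlations, and the severity-correlation coefficients
#' of the 8-miRNA and 17-gene peripheral-blood signatures derived from
#' them.
#'
#' @param which One of \code{"pairs"} (19 regulatory pairs, as a
#'   data.frame), \code{"mirna_signature"} (the 8-miRNA [Signature-class])
#'   or \code{"gene_signature"} (the 17-gene [Signature-class]).
#' @return A data.frame or a [Signature-class], see \code{which}.
#' @examples
#' sarcoidosisFixture("gene_signature")
#' nrow(sarcoidosisFixture("pairs"))
#' @export
sarcoidosisFixture <- function(which = c("pairs", "mirna_signature",
                                         "gene_signature")) {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("sarcoidosis_", which, ".tsv"),
                        package = "sarcoSig", mustWork = TRUE)
    lines <- .read_tsv_lines(path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    col <- function(nm) vapply(body, `[[`, character(1L), match(nm, header))
    if (which == "pairs") {
        data.frame(
            mirna_id = col("mirna_id"),
            gene_symbol = col("gene_symbol"),
            mirsvr_score = as.numeric(col("mirsvr_score")),
            pair_rho = as.numeric(col("pair_rho")),
            pair_adj_p = as.numeric(col("pair_adj_p")))
    } else {
        Signature(
            name = if (which == "mirna_signature") "8-miRNA signature"
                   else "17-gene signature",
            platform = if (which == "mirna_signature") "miRNA" else "mRNA",
            featureIds = col("feature_id"),
            rho = as.numeric(col("rho")))
    }
}
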