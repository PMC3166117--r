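#' Read a feature-by-sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers, a first column of
#' feature identifiers, and a numeric body.  Values tagged `log2` are
#' exponentiated (base 2) on load so that the returned object is always on the
#' linear intensity scale.
#'
#' @param path path to a tab-separated file.
#' @param scale encoding of the file: `"linear"` (default) or `"log2"`.
#' @param sampleData optional sample metadata `data.frame` (see
#'   [readSampleMetadata()]).
#' @return An [IntensityExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "f1\t1\t2", "f2\t3\t4"), tf)
#' intensities(readExpressionMatrix(tf))
#' intensities(readExpressionMatrix(tf, scale = "log2"))
#' @export
readExpressionMatrix <- function(path, scale = c("linear", "log2"),
                                 sampleData = NULL) {
    scale <- match.arg(scale)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 2)
        stop("expected a feature_id column plus at least one sample column")
    fid <- raw[[1]]
    if (anyDuplicated(fid))
        stop("duplicated feature identifiers: ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))
    sid <- colnames(raw)[-1]
    if (anyDuplicated(sid))
        stop("duplicated sample identifiers: ",
             paste(unique(sid[duplicated(sid)]), collapse = ", "))
    body <- as.matrix(raw[, -1, drop = FALSE])
    values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                      dimnames = list(fid, sid)))
    if (anyNA(values)) {
        bad <- which(is.na(values), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                     fid[bad[1]], sid[bad[2]]))
    }
    if (scale == "log2") values <- 2^values
    IntensityExperiment(values, sampleData = sampleData)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()]; full precision is preserved so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param x An [IntensityExperiment-class].
#' @param path output path.
#' @param scale write linear intensities (default) or their log2.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    v <- intensities(x)
    if (scale == "log2") v <- log2(v)
    df <- data.frame(feature_id = rownames(v),
                     format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns `sample_id`, `dataset_id`, `tissue`, `condition`.
#'
#' @param path path to a tab-separated file.
#' @return A `data.frame` with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    md <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    need <- c("sample_id", "dataset_id", "tissue", "condition")
    miss <- setdiff(need, names(md))
    if (length(miss))
        stop("sample metadata is missing columns: ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        stop("duplicated sample_id in metadata")
    md
}

#' Restrict two matrices to their common samples
#'
#' Both matrices are reduced to the intersection of their sample identifiers,
#' in the sample order of the miRNA matrix.  Dropped samples are reported via
#' a warning.
#'
#' @param mirna,genes [IntensityExperiment-class] objects.
#' @return A list with elements `mirna` and `genes`.
#' @export
matchSamples <- function(mirna, genes) {
    sm <- colnames(mirna); sg <- colnames(genes)
    common <- sm[sm %in% sg]
    if (!length(common))
        stop("no samples in common between the two matrices")
    dropped <- c(setdiff(sm, common), setdiff(sg, common))
    if (length(dropped))
        warning("dropping samples absent from one matrix: ",
                paste(dropped, collapse = ", "))
    list(mirna = mirna[, common], genes = genes[, common])
}

#' Dataset-level expression threshold
#'
#' The threshold separating "expressed" from "not expressed" calls is the
#' median over \emph{all} entries of the intensity matrix (for an even count,
#' the mean of the two central order statistics).
#'
#' @param x An [IntensityExperiment-class] or numeric matrix.
#' @return A single numeric threshold.
#' @examples
#' m <- matrix(1:9, 3, dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
#' expressionThreshold(IntensityExperiment(m))  # 5
#' @export
expressionThreshold <- function(x) {
    v <- if (is(x, "IntensityExperiment")) intensities(x) else as.matrix(x)
    if (!length(v)) stop("cannot take the median of an empty matrix")
    stats::median(as.vector(v))
}

#' Per-cell expression calls
#'
#' A feature is called expressed in a sample iff its intensity is strictly
#' greater than the threshold; ties at the threshold are \emph{not} expressed.
#'
#' @param x An [IntensityExperiment-class] or numeric matrix.
#' @param threshold expression cutoff, normally [expressionThreshold()] of the
#'   same matrix.
#' @return A logical matrix with the dimensions of `x`.
#' @export
callExpressed <- function(x, threshold = expressionThreshold(x)) {
    v <- if (is(x, "IntensityExperiment")) intensities(x) else as.matrix(x)
    v > threshold
}
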