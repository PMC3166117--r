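#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   findOverlaps granges
#' @importFrom IRanges IRanges
NULL

#' Container for a feature-by-sample intensity matrix
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding non-negative,
#' linear-scale expression intensities in a single assay named
#' \code{"intensity"}.  Inputs encoded as log2 are exponentiated on load by
#' [readExpressionMatrix()], so every \code{IntensityExperiment} is on the
#' linear scale.  Sample metadata (tissue, condition, dataset) lives in
#' \code{colData}.
#'
#' Validity requires unique feature and sample identifiers and finite,
#' non-negative values.
#'
#' @seealso [IntensityExperiment()], [readExpressionMatrix()]
#' @exportClass IntensityExperiment
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
    if (!"intensity" %in% names(SummarizedExperiment::assays(object)))
        return("assay 'intensity' is missing")
    v <- SummarizedExperiment::assay(object, "intensity")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("feature and sample identifiers are required")
    if (anyDuplicated(rownames(v)))
        return("duplicated feature identifiers")
    if (anyDuplicated(colnames(v)))
        return("duplicated sample identifiers")
    if (!is.numeric(v) || any(!is.finite(v)))
        return("intensities must be finite numbers")
    if (any(v < 0))
        return("intensities must be >= 0")
    TRUE
})

#' Construct an IntensityExperiment
#'
#' @param values numeric feature-by-sample matrix with row and column names;
#'   linear-scale intensities, all finite and \eqn{\ge 0}.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata,
#'   one row per column of `values` (matched by `sample_id` column or row
#'   names).
#' @return An [IntensityExperiment-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' IntensityExperiment(m)
#' @export
IntensityExperiment <- function(values, sampleData = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(sampleData)) {
        sampleData <- as.data.frame(sampleData)
        key <- if ("sample_id" %in% names(sampleData)) {
            as.character(sampleData$sample_id)
        } else {
            rownames(sampleData)
        }
        if (anyDuplicated(key))
            stop("duplicated sample_id in sample metadata")
        missing <- setdiff(colnames(values), key)
        if (length(missing))
            stop("samples without metadata record: ",
                 paste(missing, collapse = ", "))
        cd <- S4Vectors::DataFrame(sampleData[match(colnames(values), key), ,
                                              drop = FALSE],
                                   row.names = colnames(values))
    }
    new("IntensityExperiment",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(intensity = values), colData = cd))
}

#' Extract the intensity matrix
#'
#' @param x An [IntensityExperiment-class].
#' @return Numeric matrix of linear-scale intensities.
#' @export
intensities <- function(x) {
    stopifnot(is(x, "IntensityExperiment"))
    SummarizedExperiment::assay(x, "intensity")
}

#' Genomic annotation for genes, miRNA hairpins and mature miRNAs
#'
#' Holds three [GenomicRanges::GRanges] sets sharing one coordinate system:
#' \describe{
#'   \item{genes}{named by `gene_id`, with a `biotype` metadata column;}
#'   \item{hairpins}{pre-miRNA hairpin loci, named by `hairpin_id`;}
#'   \item{matures}{mature miRNA loci, named by `mature_id`, with
#'     `hairpin_id` and (after [assignArms()]) `arm` (`"5p"`/`"3p"`)
#'     metadata columns; an optional `name` column carries the measured
#'     (platform) identifier, which — unlike `mature_id` — may be shared by
#'     identical matures excised from hairpins at different genomic loci.}
#' }
#' Validity requires each mature to lie fully inside its hairpin on the same
#' strand, and the two matures of any hairpin to be disjoint.
#'
#' @seealso [MirnaAnnotation()], [readMirnaAnnotation()], [assignArms()]
#' @exportClass MirnaAnnotation
setClass("MirnaAnnotation",
         representation(genes = "GRanges", hairpins = "GRanges",
                        matures = "GRanges"))

setValidity("MirnaAnnotation", function(object) {
    g <- object@genes; h <- object@hairpins; m <- object@matures
    if (is.null(names(h)) && length(h)) return("hairpins must be named")
    if (length(h) && anyDuplicated(names(h)))
        return("duplicated hairpin_id")
    if (length(g) && (is.null(names(g)) || anyDuplicated(names(g))))
        return("genes must carry unique gene_id names")
    if (length(m)) {
        if (is.null(names(m)) || anyDuplicated(names(m)))
            return("matures must carry unique mature_id names")
        if (is.null(m$hairpin_id))
            return("matures must carry a hairpin_id column")
        if (!all(m$hairpin_id %in% names(h)))
            return("mature refers to unknown hairpin")
        hp <- h[m$hairpin_id]
        inside <- GenomicRanges::start(m) >= GenomicRanges::start(hp) &
            GenomicRanges::end(m) <= GenomicRanges::end(hp) &
            as.character(GenomicRanges::seqnames(m)) ==
                as.character(GenomicRanges::seqnames(hp)) &
            as.character(GenomicRanges::strand(m)) ==
                as.character(GenomicRanges::strand(hp))
        if (!all(inside))
            return(paste0("mature outside its hairpin (or strand mismatch): ",
                          paste(names(m)[!inside], collapse = ", ")))
        for (hid in unique(m$hairpin_id[duplicated(m$hairpin_id)])) {
            mm <- m[m$hairpin_id == hid]
            if (length(mm) > 2)
                return(paste0("hairpin ", hid, " has more than two matures"))
            if (GenomicRanges::start(mm[2]) <= GenomicRanges::end(mm[1]) &&
                GenomicRanges::start(mm[1]) <= GenomicRanges::end(mm[2]))
                return(paste0("overlapping matures in hairpin ", hid))
        }
    }
    TRUE
})

#' Construct a MirnaAnnotation
#'
#' @param genes,hairpins,matures `GRanges` as described in
#'   [MirnaAnnotation-class].
#' @return A validated [MirnaAnnotation-class] object.
#' @export
MirnaAnnotation <- function(genes = GRanges(), hairpins = GRanges(),
                            matures = GRanges()) {
    new("MirnaAnnotation", genes = genes, hairpins = hairpins,
        matures = matures)
}

#' @describeIn MirnaAnnotation-class gene ranges
#' @param x A `MirnaAnnotation`.
#' @export
annotatedGenes <- function(x) x@genes

#' @describeIn MirnaAnnotation-class hairpin ranges
#' @export
annotatedHairpins <- function(x) x@hairpins

#' @describeIn MirnaAnnotation-class mature miRNA ranges
#' @export
annotatedMatures <- function(x) x@matures

# measured identifier of each mature: the optional `name` column, falling
# back to the unique mature_id
.matureNames <- function(m) {
    if (!is.null(m$name)) as.character(m$name) else as.character(names(m))
}

setMethod("show", "MirnaAnnotation", function(object) {
    cat("MirnaAnnotation:", length(object@genes), "genes,",
        length(object@hairpins), "hairpins,",
        length(object@matures), "matures\n")
    arm <- object@matures$arm
    if (!is.null(arm))
        cat("  arms assigned:", sum(!is.na(arm)), "/", length(arm), "\n")
})

#' Pair-by-sample log2(5p/3p) ratio matrix
#'
#' \linkS4class{SummarizedExperiment} subclass with two assays:
#' \describe{
#'   \item{lratio}{numeric log2(5p/3p) values.  Cells where only one arm is
#'     expressed hold the sentinel value; cells where neither arm is expressed
#'     are `NA` and are excluded from distances.}
#'   \item{status}{character codes: `"B"` both arms expressed, `"5"` only the
#'     5p arm, `"3"` only the 3p arm, `"N"` neither.}
#' }
#' Sentinels are `max(finite) + 0.1` (only 5p) and `min(finite) - 0.1`
#' (only 3p), computed from the finite cells of the same matrix; they are
#' `NA` in raw (unthresholded) matrices where every cell has status `"B"`.
#' `rowData` carries the sister-pair table (`hairpin_id`, `mature5_id`,
#' `mature3_id`).
#'
#' @seealso [rawLogRatio()], [thresholdedLogRatio()], [standardizeRows()],
#'   [clusterLogRatios()]
#' @exportClass LogRatioMatrix
setClass("LogRatioMatrix", contains = "SummarizedExperiment",
         representation(sentinelHi = "numeric", sentinelLo = "numeric",
                        standardized = "logical"))

setValidity("LogRatioMatrix", function(object) {
    a <- SummarizedExperiment::assays(object)
    if (!all(c("lratio", "status") %in% names(a)))
        return("assays 'lratio' and 'status' are required")
    st <- a$status
    if (!all(st %in% c("B", "5", "3", "N")))
        return("status codes must be B/5/3/N")
    lr <- a$lratio
    if (any(is.na(lr) != (st == "N")))
        return("NA cells must coincide with status 'N'")
    if (!object@standardized && !is.na(object@sentinelHi)) {
        fin <- lr[st == "B"]
        if (length(fin) && (object@sentinelHi <= max(fin) ||
                            object@sentinelLo >= min(fin)))
            return("sentinels must lie outside the finite value range")
    }
    TRUE
})

.newLogRatioMatrix <- function(values, status, pairs, sentinelHi = NA_real_,
                               sentinelLo = NA_real_, standardized = FALSE) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(lratio = values, status = status),
        rowData = S4Vectors::DataFrame(pairs, row.names = rownames(values)))
    new("LogRatioMatrix", se, sentinelHi = sentinelHi, sentinelLo = sentinelLo,
        standardized = standardized)
}

#' @describeIn LogRatioMatrix-class the log-ratio value matrix
#' @param x A `LogRatioMatrix`.
#' @export
logRatios <- function(x) SummarizedExperiment::assay(x, "lratio")

#' @describeIn LogRatioMatrix-class the per-cell status code matrix
#' @export
ratioStatus <- function(x) SummarizedExperiment::assay(x, "status")

#' @describeIn LogRatioMatrix-class the two sentinel values, named `hi`/`lo`
#' @export
sentinels <- function(x) c(hi = x@sentinelHi, lo = x@sentinelLo)

setMethod("show", "LogRatioMatrix", function(object) {
    st <- ratioStatus(object)
    cat(class(object), "with", nrow(object), "pairs x", ncol(object),
        "samples\n")
    tab <- table(factor(st, levels = c("B", "5", "3", "N")))
    cat("  cells: both =", tab[["B"]], " only5 =", tab[["5"]],
        " only3 =", tab[["3"]], " neither =", tab[["N"]], "\n")
    if (!is.na(object@sentinelHi))
        cat(sprintf("  sentinels: hi = %.4g, lo = %.4g\n",
                    object@sentinelHi, object@sentinelLo))
    if (object@standardized) cat("  rows standardized\n")
})
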