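#' Published worked-example tables
#'
#' Small reference tables shipped with the package, summarizing five public
#' microarray series of matched miRNA (and, for four of them, gene)
#' expression: multiple myeloma and normal plasma cells (MM, GEO GSE17498),
#' acute lymphoblastic leukaemia (ALL, GSE14834), normal and Alzheimer
#' parietal cortex (ALZ, GSE16759), prostate cancer (PRO, GSE21032) and a
#' multi-cancer/normal panel (MCN, GSE14985).  They serve as worked examples
#' for the cross-dataset summary operations:
#' \describe{
#'   \item{publishedPairClassCounts()}{per-dataset sister-pair
#'     classification counts (A/AC/C/NOT_EXPRESSED), input for
#'     [classificationSummary()];}
#'   \item{publishedHostCorrelationCounts()}{per-dataset intragenic
#'     miRNA/host-gene correlation counts (positive, >0.25, >0.5, FDR<0.01),
#'     input for [summarizeCorrelations()];}
#'   \item{publishedSampleCounts()}{per-series sample sizes, flagging the
#'     three series whose samples make up the combined 211-sample
#'     strand-bias heatmap.}
#' }
#'
#' @return A `data.frame`; see each description.
#' @name publishedTables
NULL

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "SisterStrand",
                        mustWork = TRUE)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname publishedTables
#' @export
publishedPairClassCounts <- function() {
    .extdata("sister_pair_classes_published.tsv")
}

#' @rdname publishedTables
#' @export
publishedHostCorrelationCounts <- function() {
    .extdata("host_correlations_published.tsv")
}

#' @rdname publishedTables
#' @export
publishedSampleCounts <- function() {
    .extdata("dataset_samples_published.tsv")
}
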