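#' Enumerate sister 5p/3p mature pairs represented in a matrix
#'
#' One pair per hairpin whose 5p and 3p matures are both measured (present
#' among the matrix features).  Identical mature-id pairs arising from
#' hairpins at different genomic loci are kept once; hairpins with a single
#' represented mature are excluded.
#'
#' @param x A [MirnaAnnotation-class] with arms assigned.
#' @param mirna An [IntensityExperiment-class] of mature miRNA intensities
#'   (or any object with mature ids as `rownames`).
#' @return A `data.frame` with columns `pair_id`, `hairpin_id`, `mature5_id`,
#'   `mature3_id`, ordered by `pair_id`.
#' @export
enumerateSisterPairs <- function(x, mirna) {
    m <- annotatedMatures(x)
    if (!length(m)) return(data.frame(pair_id = character(),
                                      hairpin_id = character(),
                                      mature5_id = character(),
                                      mature3_id = character()))
    if (is.null(m$arm) || anyNA(m$arm))
        stop("arms are not assigned; run assignArms() first")
    feats <- rownames(mirna)
    mnames <- .matureNames(m)
    keep <- mnames %in% feats
    m <- m[keep]; mnames <- mnames[keep]
    df <- data.frame(hairpin_id = m$hairpin_id, mature_id = mnames,
                     arm = m$arm, stringsAsFactors = FALSE)
    wide <- merge(df[df$arm == "5p", c("hairpin_id", "mature_id")],
                  df[df$arm == "3p", c("hairpin_id", "mature_id")],
                  by = "hairpin_id", suffixes = c("5", "3"))
    names(wide) <- c("hairpin_id", "mature5_id", "mature3_id")
    wide <- wide[order(wide$hairpin_id), , drop = FALSE]
    key <- paste(wide$mature5_id, wide$mature3_id, sep = "\r")
    wide <- wide[!duplicated(key), , drop = FALSE]
    out <- data.frame(pair_id = wide$hairpin_id, wide,
                      stringsAsFactors = FALSE)
    rownames(out) <- out$pair_id
    out
}

.pairValues <- function(mirna, pairs) {
    v <- intensities(mirna)
    missing <- setdiff(c(pairs$mature5_id, pairs$mature3_id), rownames(v))
    if (length(missing))
        stop("matures absent from the matrix: ",
             paste(missing, collapse = ", "))
    list(x5 = v[pairs$mature5_id, , drop = FALSE],
         x3 = v[pairs$mature3_id, , drop = FALSE])
}

#' Raw per-sample log2(5p/3p) ratios
#'
#' All intensities involved must be strictly positive; zero (or sub-threshold)
#' intensities are the province of [thresholdedLogRatio()], which encodes
#' alternative expression with sentinel values instead.
#'
#' @param mirna An [IntensityExperiment-class].
#' @param pairs sister-pair table from [enumerateSisterPairs()].
#' @return A [LogRatioMatrix-class] with every cell status `"B"`.
#' @export
rawLogRatio <- function(mirna, pairs) {
    pv <- .pairValues(mirna, pairs)
    if (any(pv$x5 <= 0) || any(pv$x3 <= 0))
        stop("non-positive intensities; use thresholdedLogRatio() instead")
    values <- log2(pv$x5 / pv$x3)
    dimnames(values) <- list(pairs$pair_id, colnames(mirna))
    status <- matrix("B", nrow(values), ncol(values),
                     dimnames = dimnames(values))
    .newLogRatioMatrix(values, status, pairs)
}

#' Thresholded log2(5p/3p) ratios with sentinel imputation
#'
#' Intensities at or below the expression threshold are treated as not
#' expressed.  Cells where both arms are expressed carry the finite
#' log2-ratio; cells where only the 5p (3p) arm is expressed are set to the
#' sentinel `max(finite) + 0.1` (`min(finite) - 0.1`), the extremes being
#' taken over the finite cells of this matrix; cells where neither arm is
#' expressed are `NA` and are excluded from all distance computations.
#'
#' @inheritParams rawLogRatio
#' @param threshold expression cutoff; defaults to the dataset median
#'   ([expressionThreshold()] of `mirna`).
#' @return A [LogRatioMatrix-class].
#' @export
thresholdedLogRatio <- function(mirna, pairs,
                                threshold = expressionThreshold(mirna)) {
    pv <- .pairValues(mirna, pairs)
    e5 <- pv$x5 > threshold
    e3 <- pv$x3 > threshold
    status <- matrix("N", nrow(e5), ncol(e5),
                     dimnames = list(pairs$pair_id, colnames(mirna)))
    status[e5 & e3] <- "B"
    status[e5 & !e3] <- "5"
    status[!e5 & e3] <- "3"
    values <- matrix(NA_real_, nrow(e5), ncol(e5),
                     dimnames = dimnames(status))
    both <- status == "B"
    if (!any(both))
        stop("no sample has both arms expressed; sentinels are undefined")
    values[both] <- log2(pv$x5[both] / pv$x3[both])
    hi <- max(values[both]) + 0.1
    lo <- min(values[both]) - 0.1
    values[status == "5"] <- hi
    values[status == "3"] <- lo
    .newLogRatioMatrix(values, status, pairs, sentinelHi = hi,
                       sentinelLo = lo)
}

#' Standardize a log-ratio matrix
#'
#' Per-pair standardization (the default) subtracts the row mean and divides
#' by the row standard deviation (denominator n-1), computed over non-missing
#' cells; sentinel cells take part as ordinary values since they encode the
#' strength of alternative expression.  `axis = "global"` centres and scales
#' by the mean and sd of all non-missing cells instead.
#'
#' @param x A [LogRatioMatrix-class].
#' @param axis `"pair"` (row-wise, default) or `"global"`.
#' @return A standardized [LogRatioMatrix-class]; rows with fewer than two
#'   observed cells or zero spread are dropped with a warning.
#' @export
standardizeRows <- function(x, axis = c("pair", "global")) {
    axis <- match.arg(axis)
    v <- logRatios(x)
    st <- ratioStatus(x)
    if (axis == "global") {
        mu <- mean(v, na.rm = TRUE)
        sdev <- stats::sd(as.vector(v), na.rm = TRUE)
        if (!is.finite(sdev) || sdev == 0)
            stop("zero spread: the matrix cannot be standardized globally")
        v <- (v - mu) / sdev
        keep <- rep(TRUE, nrow(v))
    } else {
        n_obs <- rowSums(!is.na(v))
        sds <- apply(v, 1, stats::sd, na.rm = TRUE)
        keep <- n_obs >= 2 & is.finite(sds) & sds > 0
        if (!all(keep))
            warning("dropping rows with <2 observed cells or zero spread: ",
                    paste(rownames(v)[!keep], collapse = ", "))
        if (!any(keep)) stop("no standardizable rows left")
        v <- v[keep, , drop = FALSE]
        v <- t(scale(t(v)))
        st <- st[keep, , drop = FALSE]
    }
    pairs <- as.data.frame(SummarizedExperiment::rowData(x))[keep, ,
                                                             drop = FALSE]
    .newLogRatioMatrix(v, st, pairs, sentinelHi = x@sentinelHi,
                       sentinelLo = x@sentinelLo, standardized = TRUE)
}

.aggregateComparable <- function(absratios, bound, rule) {
    if (!length(absratios)) return(NA)
    agg <- switch(rule,
                  median = stats::median(absratios),
                  mean = mean(absratios),
                  all = max(absratios),
                  any = min(absratios))
    agg <= bound
}

#' Comparable-expression flag for one sister pair
#'
#' In samples where both arms are expressed, the two levels are comparable
#' when |log2(5p/3p)| does not exceed `bound` (default 1, i.e. at most a
#' two-fold difference).  The per-sample criterion is aggregated over the
#' concurrent samples by `rule`: the default compares the median |log2 ratio|
#' to the bound; `"all"`/`"any"` require all/at least one sample to meet it;
#' `"mean"` uses the mean.
#'
#' @param mirna An [IntensityExperiment-class].
#' @param mature5,mature3 feature identifiers of the two arms.
#' @param threshold expression cutoff.
#' @param bound comparability bound on |log2 ratio| (default 1.0).
#' @param rule aggregation rule over concurrent samples.
#' @return `TRUE`/`FALSE`, or `NA` when the pair has no concurrent sample.
#' @export
comparableFlag <- function(mirna, mature5, mature3,
                           threshold = expressionThreshold(mirna),
                           bound = 1.0,
                           rule = c("median", "all", "any", "mean")) {
    rule <- match.arg(rule)
    v <- intensities(mirna)
    x5 <- v[mature5, ]; x3 <- v[mature3, ]
    conc <- x5 > threshold & x3 > threshold
    .aggregateComparable(abs(log2(x5[conc] / x3[conc])), bound, rule)
}

#' Classify sister pairs as A / AC / C / NOT_EXPRESSED
#'
#' Per pair, samples where exactly one arm is expressed are \emph{alternative}
#' and samples where both are expressed are \emph{concurrent} (relative to
#' the dataset-median expression call).  Pairs that are never concurrent are
#' `A`, never alternative are `C`, both are `AC`, and neither are
#' `NOT_EXPRESSED`.
#'
#' @inheritParams rawLogRatio
#' @param threshold expression cutoff.
#' @param bound,rule comparability settings, see [comparableFlag()].
#' @return A `data.frame` with columns `pair_id`, `label`, `n_concurrent`,
#'   `n_alternative`, `comparable` (`NA` for pairs without concurrent
#'   samples).
#' @export
classifyPairs <- function(mirna, pairs,
                          threshold = expressionThreshold(mirna),
                          bound = 1.0,
                          rule = c("median", "all", "any", "mean")) {
    rule <- match.arg(rule)
    pv <- .pairValues(mirna, pairs)
    e5 <- pv$x5 > threshold
    e3 <- pv$x3 > threshold
    n_conc <- rowSums(e5 & e3)
    n_alt <- rowSums(xor(e5, e3))
    label <- ifelse(n_conc == 0 & n_alt == 0, "NOT_EXPRESSED",
             ifelse(n_conc == 0, "A",
             ifelse(n_alt == 0, "C", "AC")))
    lrat <- log2(pv$x5 / pv$x3)
    comparable <- vapply(seq_len(nrow(pairs)), function(i) {
        conc <- e5[i, ] & e3[i, ]
        .aggregateComparable(abs(lrat[i, conc]), bound, rule)
    }, NA)
    data.frame(pair_id = pairs$pair_id,
               label = factor(label,
                              levels = c("A", "AC", "C", "NOT_EXPRESSED")),
               n_concurrent = n_conc, n_alternative = n_alt,
               comparable = comparable, row.names = pairs$pair_id,
               stringsAsFactors = FALSE)
}

#' UPGMA clustering of samples or pairs on log-ratio values
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distances.
#' Missing (`"N"`) cells are excluded pairwise: the squared distance over the
#' observed dimensions is rescaled by (total dims / observed dims) before the
#' square root, which is [stats::dist()]'s behaviour.  Items are ordered
#' lexically beforehand so that tie-breaks and leaf order are deterministic.
#'
#' @param x A [LogRatioMatrix-class], typically standardized.
#' @param axis cluster `"samples"` (columns) or `"pairs"` (rows).
#' @return An object of class [stats::hclust].
#' @export
clusterLogRatios <- function(x, axis = c("samples", "pairs")) {
    axis <- match.arg(axis)
    m <- logRatios(x)
    if (axis == "samples") m <- t(m)
    if (nrow(m) < 2)
        stop("need at least two items to cluster")
    m <- m[order(rownames(m)), , drop = FALSE]
    obs <- !is.na(m)
    share <- tcrossprod(obs * 1)
    diag(share) <- NA
    lonely <- rownames(m)[apply(share, 1, max, na.rm = TRUE) == 0]
    if (length(lonely))
        stop("item(s) share no observed cell with any other item: ",
             paste(lonely, collapse = ", "))
    d <- stats::dist(m)
    stats::hclust(d, method = "average")
}

#' Newick text for a dendrogram
#'
#' @param h An [stats::hclust] object (e.g. from [clusterLogRatios()]).
#' @return A single Newick string.
#' @export
dendrogramNewick <- function(h) {
    ape::write.tree(ape::as.phylo(h))
}

#' Summarize pair classifications across datasets
#'
#' Per dataset, counts and percentages (of the full pair set) of the
#' `A`/`AC`/`C`/`NOT_EXPRESSED` labels plus the total of expressed classes;
#' across datasets, the unweighted mean and sample standard deviation (n-1)
#' of each label's percentage.
#'
#' @param x either a named list of [classifyPairs()] outputs (one per
#'   dataset), or a `data.frame` of counts with columns `dataset`, `A`, `AC`,
#'   `C`, `NOT_EXPRESSED`.
#' @return list with `per_dataset` (counts and percentages) and `cross`
#'   (label, `mean_pct`, `sd_pct`).
#' @export
classificationSummary <- function(x) {
    labs <- c("A", "AC", "C", "NOT_EXPRESSED")
    if (is.data.frame(x)) {
        counts <- x
        if (!all(c("dataset", labs) %in% names(counts)))
            stop("count input needs columns dataset, A, AC, C, NOT_EXPRESSED")
    } else {
        counts <- do.call(rbind, lapply(names(x), function(ds) {
            tab <- table(factor(x[[ds]]$label, levels = labs))
            data.frame(dataset = ds, as.list(tab), check.names = FALSE)
        }))
    }
    total <- rowSums(counts[, labs])
    per <- data.frame(counts,
                      total = total,
                      total_expressed = total - counts$NOT_EXPRESSED,
                      check.names = FALSE)
    for (l in labs)
        per[[paste0("pct_", l)]] <- 100 * counts[[l]] / total
    per$pct_expressed <- 100 * per$total_expressed / total
    cross <- data.frame(
        label = labs,
        mean_pct = vapply(labs, function(l) mean(per[[paste0("pct_", l)]]),
                          0),
        sd_pct = vapply(labs, function(l) {
            p <- per[[paste0("pct_", l)]]
            if (length(p) > 1) stats::sd(p) else NA_real_
        }, 0),
        row.names = NULL)
    list(per_dataset = per, cross = cross)
}

#' Diverging heatmap of a log-ratio matrix (cosmetic)
#'
#' Red (5p prevails) to blue (3p prevails) through white at 0, rows and
#' columns ordered by UPGMA clustering.  Requires the `pheatmap` package.
#'
#' @param x A [LogRatioMatrix-class].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plotLogRatioHeatmap <- function(x, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotLogRatioHeatmap() needs the 'pheatmap' package")
    m <- logRatios(x)
    lim <- max(abs(m), na.rm = TRUE)
    cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
    invisible(pheatmap::pheatmap(
        m, color = cols, breaks = seq(-lim, lim, length.out = 102),
        clustering_method = "average",
        clustering_distance_rows = "euclidean",
        clustering_distance_cols = "euclidean", ...))
}
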