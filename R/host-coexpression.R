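#' Pearson correlation with t-based p-value
#'
#' Two-sided p-value from the exact t transform,
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n-2 degrees of freedom.  The t
#' approximation is adequate for the sample sizes in scope (8-140); for very
#' small n a permutation p-value (seeded, `nperm` permutations of `y`,
#' \eqn{p = (1 + \#\{|r^*| \ge |r|\}) / (1 + nperm)}) is available.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param method `"t"` (default) or `"permutation"`.
#' @param nperm,permSeed permutation count and seed for the permutation
#'   method.
#' @return list with `r`, `n`, `p`.
#' @export
pearsonTest <- function(x, y, method = c("t", "permutation"),
                        nperm = 10000, permSeed = 1L) {
    method <- match.arg(method)
    n <- length(x)
    if (n != length(y)) stop("x and y must have equal length")
    if (n < 3) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero-variance profile: correlation undefined")
    r <- stats::cor(x, y)
    if (method == "permutation") {
        set.seed(permSeed)
        rstar <- vapply(seq_len(nperm),
                        function(i) stats::cor(x, sample(y)), 0)
        return(list(r = r, n = n,
                    p = (1 + sum(abs(rstar) >= abs(r) - 1e-12)) /
                        (1 + nperm)))
    }
    df <- n - 2
    if (abs(r) >= 1) return(list(r = r, n = n, p = 0))
    t <- r * sqrt(df / (1 - r^2))
    list(r = r, n = n, p = 2 * stats::pt(-abs(t), df))
}

#' Correlate intragenic mature miRNAs with host-gene expression
#'
#' Pearson correlation over matched samples for every (mature miRNA, host
#' gene) pair implied by the host assignments; two-sided p-values from the t
#' transform ([pearsonTest()]).  Pairs whose mature or host is absent from
#' the matrices, with fewer than 3 samples, or with a zero-variance profile
#' are skipped with a warning.
#'
#' @param mirna,genes sample-matched [IntensityExperiment-class] objects
#'   (see [matchSamples()]).
#' @param annotation A [MirnaAnnotation-class].
#' @param assignments output of [classifyIntragenic()]; defaults to
#'   classifying `annotation`.
#' @param scale correlate linear intensities (default) or their log2.
#' @return A `data.frame` with columns `mature_id`, `host_gene_id`, `n`, `r`,
#'   `p`.
#' @export
correlateMirnaHost <- function(mirna, genes, annotation,
                               assignments = classifyIntragenic(annotation),
                               scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    if (!identical(colnames(mirna), colnames(genes)))
        stop("matrices are not sample-matched; run matchSamples() first")
    m <- annotatedMatures(annotation)
    intra <- assignments[assignments$status == "intragenic", , drop = FALSE]
    keep <- m$hairpin_id %in% intra$hairpin_id
    map <- data.frame(
        mature_id = .matureNames(m)[keep],
        host_gene_id = intra$host_gene_id[match(m$hairpin_id[keep],
                                                intra$hairpin_id)],
        stringsAsFactors = FALSE)
    vm <- intensities(mirna); vg <- intensities(genes)
    if (scale == "log2") { vm <- log2(vm); vg <- log2(vg) }
    present <- map$mature_id %in% rownames(vm) &
        map$host_gene_id %in% rownames(vg)
    if (any(!present))
        warning(sum(!present), " miRNA/host pair(s) skipped: mature or host ",
                "gene not measured")
    map <- map[present, , drop = FALSE]
    if (ncol(vm) < 3)
        stop("need at least 3 matched samples")
    rows <- lapply(seq_len(nrow(map)), function(i) {
        x <- vm[map$mature_id[i], ]
        y <- vg[map$host_gene_id[i], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
        pt <- pearsonTest(x, y)
        data.frame(mature_id = map$mature_id[i],
                   host_gene_id = map$host_gene_id[i],
                   n = pt$n, r = pt$r, p = pt$p, stringsAsFactors = FALSE)
    })
    dropped <- sum(vapply(rows, is.null, TRUE))
    if (dropped)
        warning(dropped, " record(s) skipped for zero-variance profiles")
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(mature_id = character(),
                          host_gene_id = character(), n = integer(),
                          r = numeric(), p = numeric())
    rownames(out) <- NULL
    out
}

#' FDR adjustment of correlation records
#'
#' Adds Benjamini-Hochberg (default) or Benjamini-Yekutieli step-up adjusted
#' q-values over the record set.
#'
#' @param records `data.frame` with a `p` column.
#' @param method `"BH"` (default) or `"BY"`.
#' @return `records` with a `q` column appended.
#' @export
fdrAdjust <- function(records, method = c("BH", "BY")) {
    method <- match.arg(method)
    records$q <- stats::p.adjust(records$p, method = method)
    records
}

#' Keep the best-correlated arm per host for sister pairs
#'
#' For host genes whose hairpin produces two measured mature forms, only the
#' record with the larger miRNA-host correlation is kept (ties go to the 5p
#' arm).  Records of single-mature hosts are unchanged.
#'
#' @param records output of [correlateMirnaHost()] (optionally with `q`).
#' @param pairs sister-pair table from [enumerateSisterPairs()].
#' @return The collapsed record `data.frame`.
#' @export
collapseBestOfPair <- function(records, pairs) {
    drop <- logical(nrow(records))
    for (i in seq_len(nrow(pairs))) {
        i5 <- which(records$mature_id == pairs$mature5_id[i])
        i3 <- which(records$mature_id == pairs$mature3_id[i])
        for (h in intersect(records$host_gene_id[i5],
                            records$host_gene_id[i3])) {
            k5 <- i5[records$host_gene_id[i5] == h]
            k3 <- i3[records$host_gene_id[i3] == h]
            # tie -> keep the 5p arm
            if (records$r[k5] >= records$r[k3]) drop[k3] <- TRUE
            else drop[k5] <- TRUE
        }
    }
    records[!drop, , drop = FALSE]
}

#' Summarize miRNA/host correlations across datasets
#'
#' Per dataset: counts and percentages of records with r > 0, r > 0.25,
#' r > 0.5 and q below the FDR threshold; across datasets: unweighted mean
#' and sample sd of the positively-correlated percentage.
#'
#' @param x a named list of [fdrAdjust()]-ed record `data.frame`s, or a
#'   `data.frame` of counts with columns `dataset`, `total`, `positive`,
#'   `gt_025`, `gt_05`, `fdr`.
#' @param fdr FDR threshold for the significance row (default 0.01); ignored
#'   for count input.
#' @return list with `per_dataset` and `cross` (`mean_positive_pct`,
#'   `sd_positive_pct`).
#' @export
summarizeCorrelations <- function(x, fdr = 0.01) {
    if (is.data.frame(x)) {
        need <- c("dataset", "total", "positive", "gt_025", "gt_05", "fdr")
        if (!all(need %in% names(x)))
            stop("count input needs columns ", paste(need, collapse = ", "))
        per <- x
    } else {
        per <- do.call(rbind, lapply(names(x), function(ds) {
            rec <- x[[ds]]
            if (!nrow(rec)) warning("empty record set for dataset ", ds)
            data.frame(dataset = ds, total = nrow(rec),
                       positive = sum(rec$r > 0),
                       gt_025 = sum(rec$r > 0.25),
                       gt_05 = sum(rec$r > 0.5),
                       fdr = if (!is.null(rec$q)) sum(rec$q < fdr) else NA)
        }))
    }
    for (col in c("positive", "gt_025", "gt_05", "fdr"))
        per[[paste0("pct_", col)]] <-
            ifelse(per$total > 0, 100 * per[[col]] / per$total, 0)
    list(per_dataset = per,
         cross = data.frame(mean_positive_pct = mean(per$pct_positive),
                            sd_positive_pct = if (nrow(per) > 1)
                                stats::sd(per$pct_positive) else NA_real_))
}
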