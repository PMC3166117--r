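# Independent oracles used across the suite.  These are deliberately naive
# re-derivations (set-based UPGMA, step-up BH by hand, enumeration Wilcoxon)
# kept separate from the package implementations they check.

# naive UPGMA: clusters as index sets, average linkage over the ORIGINAL
# distance matrix; returns merge heights in merge order
upgmaOracle <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric()
    while (length(clusters) > 1) {
        best <- c(NA, NA); besth <- Inf
        for (i in seq_along(clusters)) {
            for (j in seq_along(clusters)) {
                if (j <= i) next
                h <- mean(d[clusters[[i]], clusters[[j]]])
                if (h < besth) { besth <- h; best <- c(i, j) }
            }
        }
        heights <- c(heights, besth)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# Benjamini-Hochberg step-up by hand
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (k in m:1) {
        val <- min(prev, p[o[k]] * m / k)
        q[o[k]] <- val
        prev <- val
    }
    q
}

# exact two-sided Wilcoxon rank-sum p by complete enumeration of group
# assignments, P(|U - mu| >= |u - mu|) with average ranks
wilcoxEnumOracle <- function(x, y) {
    nx <- length(x); ny <- length(y); N <- nx + ny
    r <- rank(c(x, y))
    u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    comb <- utils::combn(N, nx)
    uall <- apply(comb, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
    mean(abs(uall - mu) >= abs(u - mu) - 1e-9)
}

# small IntensityExperiment from a matrix-like spec
toyExpr <- function(values, features = NULL, samples = NULL) {
    v <- as.matrix(values)
    if (!is.null(features)) rownames(v) <- features
    if (!is.null(samples)) colnames(v) <- samples
    if (is.null(rownames(v))) rownames(v) <- paste0("f", seq_len(nrow(v)))
    if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
    IntensityExperiment(v)
}

# hand-built annotation: one + strand pair hairpin, one - strand pair
# hairpin, one single-mature hairpin, two genes (one containing hp1)
toyAnnotation <- function() {
    genes <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(500, 30000), c(20000, 31000)),
        strand = c("+", "-"))
    names(genes) <- c("GENEA", "GENEB")
    genes$biotype <- "protein_coding"
    hairpins <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1000, 40000, 50000),
                                 c(1079, 40079, 50079)),
        strand = c("+", "-", "+"))
    names(hairpins) <- c("hpA", "hpB", "hpC")
    matures <- GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(c(1005, 1055, 40005, 40055, 50005),
                         c(1026, 1076, 40026, 40076, 50026)),
        strand = c("+", "+", "-", "-", "+"))
    names(matures) <- c("mir-a-5p", "mir-a-3p", "mir-b-3p", "mir-b-5p",
                        "mir-c-5p")
    matures$hairpin_id <- c("hpA", "hpA", "hpB", "hpB", "hpC")
    matures$arm <- NA_character_
    assignArms(MirnaAnnotation(genes = genes, hairpins = hairpins,
                               matures = matures))
}
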