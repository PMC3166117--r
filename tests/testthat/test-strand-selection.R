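# matrix covering the toy annotation's measurable matures
.toyMirna <- function(values5, values3, samples = NULL, extra = NULL) {
    v <- rbind("mir-a-5p" = values5, "mir-a-3p" = values3)
    if (!is.null(extra)) v <- rbind(v, extra)
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(v)))
    colnames(v) <- samples
    IntensityExperiment(v)
}

test_that("sister pairs are enumerated once per represented hairpin", {
    ann <- toyAnnotation()
    x <- .toyMirna(c(8, 8), c(2, 2),
                   extra = rbind("mir-b-5p" = c(1, 1), "mir-b-3p" = c(1, 1),
                                 "mir-c-5p" = c(5, 5)))
    pairs <- enumerateSisterPairs(ann, x)
    expect_setequal(pairs$pair_id, c("hpA", "hpB"))
    expect_identical(pairs["hpA", "mature5_id"], "mir-a-5p")
    expect_identical(pairs["hpB", "mature3_id"], "mir-b-3p")

    # hairpin with a single measured mature yields no pair
    x2 <- .toyMirna(c(8, 8), c(2, 2), extra = rbind("mir-b-5p" = c(1, 1)))
    expect_identical(enumerateSisterPairs(ann, x2)$pair_id, "hpA")
})

test_that("identical mature pairs from different loci collapse to one", {
    # miRBase situation: a second locus has distinct record ids but the
    # measured mature names are shared, so one measured pair results
    ann <- toyAnnotation()
    g <- annotatedGenes(ann)
    h <- c(annotatedHairpins(ann)["hpA"],
           GenomicRanges::GRanges("chr1", IRanges::IRanges(90000, 90079),
                                  "+"))
    names(h) <- c("hpA", "hpA2")
    m0 <- annotatedMatures(ann)[c("mir-a-5p", "mir-a-3p")]
    m0$name <- names(m0)
    dup <- GenomicRanges::shift(m0, 89000)
    names(dup) <- paste0(names(m0), "_2")
    dup$hairpin_id <- "hpA2"
    dup$name <- m0$name
    ann2 <- assignArms(MirnaAnnotation(genes = g, hairpins = h,
                                       matures = c(m0, dup)))
    x <- .toyMirna(c(8, 8), c(2, 2))
    pairs <- enumerateSisterPairs(ann2, x)
    expect_equal(nrow(pairs), 1L)
    expect_identical(pairs$pair_id, "hpA")
    expect_identical(pairs$mature5_id, "mir-a-5p")
})

test_that("raw log ratios are antisymmetric and reject non-positive input", {
    ann <- toyAnnotation()
    x <- .toyMirna(c(8, 4), c(2, 4))
    pairs <- enumerateSisterPairs(ann, x)
    lrm <- rawLogRatio(x, pairs)
    expect_equal(as.vector(logRatios(lrm)), c(2, 0))
    expect_true(all(ratioStatus(lrm) == "B"))

    # swapping the arms negates every cell
    swapped <- pairs
    swapped$mature5_id <- pairs$mature3_id
    swapped$mature3_id <- pairs$mature5_id
    expect_equal(logRatios(rawLogRatio(x, swapped)),
                 -logRatios(lrm))

    x0 <- .toyMirna(c(8, 0), c(2, 4))
    expect_error(rawLogRatio(x0, pairs), "thresholdedLogRatio")
})

test_that("thresholded ratios assign sentinels from the finite extremes", {
    ann <- toyAnnotation()
    # threshold 1: finite cells span [-3, 2.5]; s3 has only the 5p arm
    # expressed (-> 2.6), s4 only the 3p arm (-> -3.1), s5 neither
    x5 <- c(2^3, 2^1.1, 4, 0.5, 0.9)
    x3 <- c(2^0.5, 2^4.1, 0.5, 6, 0.8)
    x <- .toyMirna(x5, x3)
    pairs <- enumerateSisterPairs(ann, x)
    lrm <- thresholdedLogRatio(x, pairs, threshold = 1)
    expect_identical(as.vector(ratioStatus(lrm)), c("B", "B", "5", "3", "N"))
    expect_equal(unname(sentinels(lrm)["hi"]), 2.6)
    expect_equal(unname(sentinels(lrm)["lo"]), -3.1)
    v <- as.vector(logRatios(lrm))
    expect_equal(v[1:4], c(2.5, -3, 2.6, -3.1))
    expect_true(is.na(v[5]))
})

test_that("sentinels sit 0.1 beyond the finite range on both sides", {
    ann <- toyAnnotation()
    set.seed(3)
    n <- 30
    x5 <- 2^runif(n, 1, 4); x3 <- 2^runif(n, 1, 4)
    x5[1] <- 8; x3[1] <- 0.5   # only 5p expressed at threshold 1
    x5[2] <- 0.5; x3[2] <- 8   # only 3p
    x <- .toyMirna(x5, x3)
    pairs <- enumerateSisterPairs(ann, x)
    lrm <- thresholdedLogRatio(x, pairs, threshold = 1)
    fin <- logRatios(lrm)[ratioStatus(lrm) == "B"]
    expect_equal(unname(sentinels(lrm)["hi"]), max(fin) + 0.1)
    expect_equal(unname(sentinels(lrm)["lo"]), min(fin) - 0.1)
    expect_gt(sentinels(lrm)["hi"], max(fin))
    expect_lt(sentinels(lrm)["lo"], min(fin))
    expect_error(thresholdedLogRatio(x, pairs, threshold = 1e9),
                 "sentinels are undefined")
})

test_that("row standardization gives mean 0, sd 1 over observed cells", {
    ann <- toyAnnotation()
    x <- .toyMirna(c(2, 4, 8, 2), c(1, 1, 1, 0.5),
                   extra = rbind("mir-b-5p" = c(4, 4, 4, 4),
                                 "mir-b-3p" = c(2, 2, 2, 2)))
    pairs <- enumerateSisterPairs(ann, x)
    lrm <- rawLogRatio(x, pairs)
    expect_warning(z <- standardizeRows(lrm), "hpB")  # zero-spread row drops
    expect_equal(nrow(z), 1L)
    expect_equal(mean(logRatios(z)), 0)
    expect_equal(sd(as.vector(logRatios(z))), 1)
    expect_equal(as.vector(logRatios(z)),
                 as.vector(scale(c(1, 2, 3, 2))))
})

test_that("standardization masks missing cells and supports global axis", {
    v <- matrix(c(1, 2, 3, NA), 1,
                dimnames = list("p1", paste0("s", 1:4)))
    st <- matrix(c("B", "B", "B", "N"), 1, dimnames = dimnames(v))
    lrm <- SisterStrand:::.newLogRatioMatrix(
        v, st, data.frame(pair_id = "p1", row.names = "p1"))
    z <- standardizeRows(lrm)
    expect_equal(as.vector(logRatios(z))[1:3], c(-1, 0, 1))
    expect_true(is.na(logRatios(z)[1, 4]))

    zg <- standardizeRows(lrm, axis = "global")
    expect_equal(mean(logRatios(zg), na.rm = TRUE), 0)
})

test_that("pair classification covers the A/AC/C/NOT_EXPRESSED definitions", {
    ann <- toyAnnotation()
    cases <- list(
        list(x5 = c(6, 7), x3 = c(2, 1), label = "A"),
        list(x5 = c(6, 6), x3 = c(7, 2), label = "AC"),
        list(x5 = c(6, 8), x3 = c(7, 9), label = "C"),
        list(x5 = c(1, 3), x3 = c(2, 4), label = "NOT_EXPRESSED"))
    for (cs in cases) {
        x <- .toyMirna(cs$x5, cs$x3)
        pairs <- enumerateSisterPairs(ann, x)
        cls <- classifyPairs(x, pairs, threshold = 5)
        expect_identical(as.character(cls$label), cs$label)
        expect_equal(cls$n_concurrent + cls$n_alternative,
                     sum(cs$x5 > 5 | cs$x3 > 5))
    }
})

test_that("swapping arm labels preserves classification labels", {
    ann <- toyAnnotation()
    set.seed(21)
    x <- .toyMirna(2^runif(12, 0, 4), 2^runif(12, 0, 4))
    pairs <- enumerateSisterPairs(ann, x)
    swapped <- pairs
    swapped$mature5_id <- pairs$mature3_id
    swapped$mature3_id <- pairs$mature5_id
    thr <- expressionThreshold(x)
    a <- classifyPairs(x, pairs, thr)
    b <- classifyPairs(x, swapped, thr)
    expect_identical(as.character(a$label), as.character(b$label))
    lrm_a <- thresholdedLogRatio(x, pairs, thr)
    lrm_b <- thresholdedLogRatio(x, swapped, thr)
    sa <- ratioStatus(lrm_a); sb <- ratioStatus(lrm_b)
    expect_identical(sa == "B", sb == "B")
    expect_identical(sa == "5", sb == "3")
    expect_equal(logRatios(lrm_a)[sa == "B"], -logRatios(lrm_b)[sb == "B"])
})

test_that("comparability uses |log2 ratio| <= bound with the chosen rule", {
    ann <- toyAnnotation()
    # single concurrent sample at exactly two-fold: |log2| = 1, comparable
    x <- .toyMirna(6, 12)
    expect_true(comparableFlag(x, "mir-a-5p", "mir-a-3p", threshold = 5))
    x2 <- .toyMirna(6, 25)
    expect_false(comparableFlag(x2, "mir-a-5p", "mir-a-3p", threshold = 5))
    # no concurrent sample -> NA
    x3 <- .toyMirna(6, 2)
    expect_true(is.na(comparableFlag(x3, "mir-a-5p", "mir-a-3p",
                                     threshold = 5)))
    # rules: ratios |log2| = (0.2, 2.06): median fails bound, "any" passes
    x4 <- .toyMirna(c(6, 25), c(6 * 2^0.2, 6))
    expect_false(comparableFlag(x4, "mir-a-5p", "mir-a-3p", threshold = 5,
                                rule = "median"))
    expect_true(comparableFlag(x4, "mir-a-5p", "mir-a-3p", threshold = 5,
                               rule = "any"))
    expect_false(comparableFlag(x4, "mir-a-5p", "mir-a-3p", threshold = 5,
                                rule = "all"))
})

test_that("UPGMA reproduces the hand-worked 1-D example", {
    v <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
    st <- matrix("B", 3, 1, dimnames = dimnames(v))
    lrm <- SisterStrand:::.newLogRatioMatrix(
        v, st, data.frame(pair_id = c("a", "b", "c"),
                          row.names = c("a", "b", "c")))
    h <- clusterLogRatios(lrm, axis = "pairs")
    expect_equal(h$height, c(1, 9.5))
})

test_that("UPGMA equals the brute-force oracle on random matrices", {
    set.seed(17)
    for (i in 1:30) {
        n <- sample(3:7, 1)
        m <- matrix(rnorm(n * 4), n,
                    dimnames = list(sprintf("i%02d", 1:n), paste0("s", 1:4)))
        st <- matrix("B", n, 4, dimnames = dimnames(m))
        lrm <- SisterStrand:::.newLogRatioMatrix(
            m, st, data.frame(pair_id = rownames(m),
                              row.names = rownames(m)))
        h <- clusterLogRatios(lrm, axis = "pairs")
        expect_equal(sort(h$height), sort(upgmaOracle(dist(m))),
                     tolerance = 1e-12)
    }
})

test_that("identical columns merge at height zero", {
    v <- matrix(c(1, 2, 1, 2, 5, 6), 2,
                dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
    st <- matrix("B", 2, 3, dimnames = dimnames(v))
    lrm <- SisterStrand:::.newLogRatioMatrix(
        v, st, data.frame(pair_id = c("p1", "p2"),
                          row.names = c("p1", "p2")))
    h <- clusterLogRatios(lrm, axis = "samples")
    expect_equal(min(h$height), 0)
})

test_that("missing cells use rescaled pairwise-complete distances", {
    v <- matrix(c(0, 1, 2, 2, NA, 5), 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
    st <- matrix(c("B", "B", "B", "B", "N", "B"), 2, byrow = TRUE,
                 dimnames = dimnames(v))
    lrm <- SisterStrand:::.newLogRatioMatrix(
        v, st, data.frame(pair_id = c("p1", "p2"),
                          row.names = c("p1", "p2")))
    h <- clusterLogRatios(lrm, axis = "pairs")
    expect_equal(h$height, sqrt((4 + 9) * 3 / 2))

    # an item with no shared observed dimension is an error naming it
    v2 <- matrix(c(1, 2, NA, NA, NA, NA, 3, 4), 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
    st2 <- ifelse(is.na(v2), "N", "B")
    lrm2 <- SisterStrand:::.newLogRatioMatrix(
        v2, st2, data.frame(pair_id = c("p1", "p2"),
                            row.names = c("p1", "p2")))
    expect_error(clusterLogRatios(lrm2, axis = "pairs"), "p1")
})

test_that("dendrograms export as Newick text", {
    v <- matrix(rnorm(12), 3, dimnames = list(c("a", "b", "c"),
                                              paste0("s", 1:4)))
    h <- hclust(dist(v), "average")
    nwk <- dendrogramNewick(h)
    expect_match(nwk, "^\\(.*\\);$")
    expect_true(all(grepl("a|b|c", nwk)))
})

test_that("classification summary reproduces per-dataset percentages", {
    counts <- data.frame(dataset = "D1", A = 1, AC = 1, C = 2,
                         NOT_EXPRESSED = 0)
    s <- classificationSummary(counts)
    expect_equal(s$per_dataset$pct_A, 25)
    expect_equal(s$per_dataset$pct_AC, 25)
    expect_equal(s$per_dataset$pct_C, 50)
    expect_equal(s$per_dataset$pct_NOT_EXPRESSED, 0)

    # identical datasets have sd 0
    two <- rbind(counts, transform(counts, dataset = "D2"))
    s2 <- classificationSummary(two)
    expect_true(all(s2$cross$sd_pct == 0))
})

test_that("cross-dataset mean/sd of AC percentages matches the worked case", {
    pct <- c(78.9, 83.1, 18.9, 59.4, 60.8)
    counts <- data.frame(dataset = paste0("D", 1:5),
                         A = 0, AC = round(pct * 10), C = 0,
                         NOT_EXPRESSED = round((100 - pct) * 10))
    s <- classificationSummary(counts)
    ac <- s$cross[s$cross$label == "AC", ]
    expect_equal(round(ac$mean_pct), 60)
    expect_equal(round(ac$sd_pct), 25)
})
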