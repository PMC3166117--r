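#' Read gene / hairpin / mature miRNA annotation from GFF3
#'
#' Understands the miRBase-style conventions: feature types `gene`,
#' `miRNA_primary_transcript` (hairpins) and `miRNA` (matures), identifiers in
#' the `ID` attribute and the mature-to-hairpin link in `Derives_from`.
#'
#' @param path path to a GFF3 file.
#' @param assign assign 5p/3p arms on load via [assignArms()] (default TRUE).
#' @return A [MirnaAnnotation-class].
#' @export
readMirnaAnnotation <- function(path, assign = TRUE) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    pick <- function(keep) {
        x <- granges(gr[keep])
        names(x) <- gr$ID[keep]
        x
    }
    genes <- pick(type == "gene")
    if (length(genes))
        genes$biotype <- if (!is.null(gr$biotype)) {
            as.character(gr$biotype[type == "gene"])
        } else {
            "protein_coding"
        }
    hairpins <- pick(type == "miRNA_primary_transcript")
    matures <- pick(type == "miRNA")
    if (length(matures)) {
        if (is.null(gr$Derives_from))
            stop("mature miRNA records lack a Derives_from attribute")
        matures$hairpin_id <- as.character(gr$Derives_from[type == "miRNA"])
        matures$arm <- NA_character_
        if (!is.null(gr$Name))
            matures$name <- as.character(gr$Name[type == "miRNA"])
    }
    ann <- MirnaAnnotation(genes = genes, hairpins = hairpins,
                           matures = matures)
    if (assign && length(matures)) ann <- assignArms(ann) else ann
}

#' Write a MirnaAnnotation to GFF3
#'
#' @param x A [MirnaAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMirnaAnnotation <- function(x, path) {
    blocks <- list()
    g <- annotatedGenes(x)
    if (length(g)) {
        gg <- granges(g)
        gg$type <- "gene"; gg$ID <- names(gg); gg$biotype <- g$biotype
        names(gg) <- NULL
        blocks$genes <- gg
    }
    h <- annotatedHairpins(x)
    if (length(h)) {
        hh <- granges(h)
        hh$type <- "miRNA_primary_transcript"; hh$ID <- names(hh)
        names(hh) <- NULL
        blocks$hairpins <- hh
    }
    m <- annotatedMatures(x)
    if (length(m)) {
        mm <- granges(m)
        mm$type <- "miRNA"; mm$ID <- names(mm)
        mm$Name <- .matureNames(m)
        mm$Derives_from <- m$hairpin_id
        names(mm) <- NULL
        blocks$matures <- mm
    }
    all <- suppressWarnings(do.call(c, unname(blocks)))
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Assign 5p/3p arms to mature miRNAs
#'
#' Arm labels follow the physical 5' to 3' order of mature sequences in the
#' precursor transcript: on the `+` strand the mature with the smaller genomic
#' start is the 5p arm; on the `-` strand the mature with the larger start is.
#' A hairpin with a single mature gets the arm implied by the position of the
#' mature midpoint relative to the hairpin midpoint.
#'
#' @param x A [MirnaAnnotation-class] (matures within hairpins on the same
#'   strand; construction already enforces this).
#' @return `x` with the `arm` column of its matures filled in.
#' @export
assignArms <- function(x) {
    m <- annotatedMatures(x)
    if (!length(m)) return(x)
    h <- annotatedHairpins(x)[m$hairpin_id]
    plus <- as.character(strand(m)) == "+"
    mid_m <- (start(m) + end(m)) / 2
    mid_h <- (start(h) + end(h)) / 2
    # single-mature default: midpoint rule, orientation-aware
    arm <- ifelse(xor(mid_m <= mid_h, !plus), "5p", "3p")
    paired <- m$hairpin_id[duplicated(m$hairpin_id)]
    for (hid in paired) {
        i <- which(m$hairpin_id == hid)
        first5 <- xor(start(m)[i[1]] < start(m)[i[2]], !plus[i[1]])
        arm[i] <- if (first5) c("5p", "3p") else c("3p", "5p")
    }
    m$arm <- arm
    MirnaAnnotation(genes = annotatedGenes(x), hairpins = annotatedHairpins(x),
                    matures = m)
}

#' Classify hairpins as intragenic or intergenic
#'
#' A hairpin is intragenic iff some gene span fully contains it (and lies on
#' the same strand when `requireSameStrand`).  When several genes qualify, the
#' shortest containing gene is taken as the host (ties broken by lexical
#' `gene_id`) and the ambiguity is reported via a message.
#'
#' @param x A [MirnaAnnotation-class].
#' @param requireSameStrand require host gene and hairpin on the same strand
#'   (default TRUE; intragenic miRNAs are candidates for co-transcription from
#'   the host promoter, which presumes sense orientation).
#' @return A `data.frame` with columns `hairpin_id`, `status`
#'   (`"intragenic"`/`"intergenic"`), `host_gene_id` (`NA` for intergenic)
#'   and `n_containing_genes`.
#' @export
classifyIntragenic <- function(x, requireSameStrand = TRUE) {
    h <- annotatedHairpins(x)
    g <- annotatedGenes(x)
    out <- data.frame(hairpin_id = as.character(names(h)),
                      status = rep("intergenic", length(h)),
                      host_gene_id = rep(NA_character_, length(h)),
                      n_containing_genes = rep(0L, length(h)),
                      stringsAsFactors = FALSE)
    if (!length(h) || !length(g)) return(out)
    ov <- GenomicRanges::findOverlaps(h, g, type = "within",
                                      ignore.strand = !requireSameStrand)
    if (!length(ov)) return(out)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    n_amb <- 0L
    for (i in unique(qh)) {
        cand <- sh[qh == i]
        out$n_containing_genes[i] <- length(cand)
        ord <- order(width(g)[cand], names(g)[cand])
        if (length(cand) > 1) n_amb <- n_amb + 1L
        out$status[i] <- "intragenic"
        out$host_gene_id[i] <- names(g)[cand[ord[1]]]
    }
    if (n_amb)
        message(n_amb, " hairpin(s) contained in several genes; ",
                "shortest containing gene chosen as host")
    out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test on the Mann-Whitney U statistic.  When both groups have at
#' most 12 observations the p-value is exact: from the null U distribution
#' when there are no ties, otherwise by complete enumeration of all group
#' assignments (with average ranks), defining
#' \eqn{p = P(|U - \mu| \ge |u - \mu|)}.  Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors.
#' @return list with `U` (for `x`), `p`, and `method` used.
#' @export
wilcoxonRankSum <- function(x, y) {
    nx <- length(x); ny <- length(y)
    if (!nx || !ny) stop("both groups must be non-empty")
    r <- rank(c(x, y))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    ties <- table(r)
    has_ties <- any(ties > 1)
    N <- nx + ny
    if (max(nx, ny) <= 12 && (!has_ties || choose(N, nx) <= 1e6)) {
        if (!has_ties) {
            p <- if (U > mu) {
                2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
            } else if (U < mu) {
                2 * stats::pwilcox(U, nx, ny)
            } else 1
            method <- "exact"
        } else {
            comb <- utils::combn(N, nx)
            Uall <- colSums(matrix(r[comb], nrow = nx)) - nx * (nx + 1) / 2
            p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
            method <- "exact enumeration (ties)"
        }
    } else {
        sig2 <- nx * ny / 12 *
            ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sig2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
        z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sig2)
        p <- 2 * stats::pnorm(-abs(z))
        method <- "normal approximation"
    }
    list(U = U, p = min(p, 1), method = method)
}

#' Compare host-gene lengths with the remaining genes
#'
#' Gene span (full genomic extent, intron-inclusive) of host genes versus all
#' other genes, with a two-sided Wilcoxon rank-sum test
#' ([wilcoxonRankSum()]).
#'
#' @param genes a named `GRanges` of gene spans (e.g. `annotatedGenes(x)`).
#' @param hostIds character vector of host `gene_id`s; must be a subset of
#'   `names(genes)`.
#' @return list with `n_host`, `n_rest`, `mean_host`, `mean_rest`, `ratio`
#'   (host/rest) and `wilcoxon_p`.
#' @export
hostLengthComparison <- function(genes, hostIds) {
    hostIds <- unique(hostIds[!is.na(hostIds)])
    if (!all(hostIds %in% names(genes)))
        stop("hostIds must be a subset of the gene identifiers")
    len <- width(genes)
    host <- len[names(genes) %in% hostIds]
    rest <- len[!names(genes) %in% hostIds]
    if (!length(host) || !length(rest))
        stop("both the host and the remaining gene group must be non-empty")
    w <- wilcoxonRankSum(host, rest)
    list(n_host = length(host), n_rest = length(rest),
         mean_host = mean(host), mean_rest = mean(rest),
         ratio = mean(host) / mean(rest), wilcoxon_p = w$p)
}

#' Count intragenic miRNAs and multi-miRNA host genes
#'
#' @param assignments output of [classifyIntragenic()].
#' @param x the [MirnaAnnotation-class] the assignments were computed from.
#' @return list with `n_intragenic_mirnas` (distinct mature miRNAs of
#'   intragenic hairpins), `n_host_genes`, `n_hosts_with_2plus` (host genes
#'   hosting at least two mature miRNAs; a single two-arm hairpin counts),
#'   `frac_hosts_with_2plus`, and the hairpin-level analogues
#'   `n_hosts_with_2plus_hairpins` / `frac_hosts_with_2plus_hairpins`.
#' @export
countMultiMirnaHosts <- function(assignments, x) {
    intra <- assignments[assignments$status == "intragenic", , drop = FALSE]
    m <- annotatedMatures(x)
    keep <- m$hairpin_id %in% intra$hairpin_id
    host_of <- intra$host_gene_id[match(m$hairpin_id[keep], intra$hairpin_id)]
    per_host <- table(host_of)
    per_host_hp <- table(intra$host_gene_id)
    n2 <- sum(per_host >= 2)
    n2hp <- sum(per_host_hp >= 2)
    nh <- length(per_host)
    list(n_intragenic_mirnas = sum(keep),
         n_host_genes = nh,
         n_hosts_with_2plus = n2,
         frac_hosts_with_2plus = if (nh) n2 / nh else 0,
         n_hosts_with_2plus_hairpins = n2hp,
         frac_hosts_with_2plus_hairpins = if (nh) n2hp / nh else 0)
}
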