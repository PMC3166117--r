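#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults define
#' the reference study conditions used throughout the test suite: two tissue
#' groups of 20 samples, 50 sister pairs per expression mode, planted log2
#' arm levels at `baseline_mean` ± 3`baseline_sd` and Gaussian noise
#' `noise_sd` on the log2 scale.
#'
#' Expression modes and the pair class they generate:
#' \describe{
#'   \item{fixed_bias}{both arms expressed, constant arm offset of
#'     ±`bias_magnitude` everywhere (one arm always prevails) — class C;}
#'   \item{tissue_flip}{both arms expressed, the sign of the offset flips
#'     between tissue groups (regulated strand selection) — class C;}
#'   \item{concurrent_comparable}{both arms high with |offset| = 0.5 < 1 —
#'     class C, comparable levels;}
#'   \item{alternative}{one arm above and the other below the dataset
#'     threshold in every sample — class A;}
#'   \item{silent}{both arms low — class NOT_EXPRESSED.}
#' }
#' `n_background` single-mature hairpins with broad baseline profiles make
#' the dataset-median expression call land between the silent and expressed
#' intensity masses, as it does on real arrays.
#'
#' @param seed integer seed; every random stream of the generator derives
#'   from it deterministically.
#' @param n_tissues,samples_per_tissue sample layout.
#' @param n_pairs_per_mode named vector of pair counts for the five modes.
#' @param bias_magnitude log2 arm offset of biased modes.
#' @param noise_sd per-cell Gaussian noise, log2 units.
#' @param baseline_mean,baseline_sd log2 intensity baseline of the dataset.
#' @param n_background number of single-mature background hairpins.
#' @param n_genes number of genes.
#' @param frac_intragenic fraction of hairpins placed fully inside a gene
#'   (same strand).
#' @param frac_multi_mirna_hosts fraction of host genes hosting two hairpins.
#' @param mean_gene_length mean span of non-host genes, nt (default 30 kb,
#'   the human average gene span).
#' @param host_length_factor host genes are on average this many times longer
#'   (default 6).
#' @param gene_length_sdlog log-scale sd of the gene length distribution
#'   (default 0.5: lengths spread over roughly an order of magnitude while
#'   group means stay estimable at a few hundred genes).
#' @param host_coupling_rho planted miRNA/host-gene correlation (Gaussian
#'   copula on the log2 scale).
#' @param gene_noise_sd within-profile sd of gene expression, log2 units.
#' @param n_true_targets number of planted true target relations.
#' @param true_target_r planted (negative) regulator/target correlation.
#' @param n_decoy_predictions number of decoy predicted relations.
#' @param n_validated validated relations sampled from the true ones.
#' @return A validated `SimulationConfig` (named list).
#' @export
simulationConfig <- function(seed = 1L,
                             n_tissues = 2L,
                             samples_per_tissue = 20L,
                             n_pairs_per_mode = c(fixed_bias = 50L,
                                                  tissue_flip = 50L,
                                                  concurrent_comparable = 50L,
                                                  alternative = 50L,
                                                  silent = 50L),
                             bias_magnitude = 2,
                             noise_sd = 0.1,
                             baseline_mean = 8,
                             baseline_sd = 1,
                             n_background = 400L,
                             n_genes = 500L,
                             frac_intragenic = 0.45,
                             frac_multi_mirna_hosts = 0.1,
                             mean_gene_length = 30000,
                             host_length_factor = 6,
                             gene_length_sdlog = 0.5,
                             host_coupling_rho = 0.3,
                             gene_noise_sd = 0.5,
                             n_true_targets = 100L,
                             true_target_r = -0.7,
                             n_decoy_predictions = 1000L,
                             n_validated = 20L) {
    modes <- c("fixed_bias", "tissue_flip", "concurrent_comparable",
               "alternative", "silent")
    full <- stats::setNames(rep(0L, 5), modes)
    full[names(n_pairs_per_mode)] <- as.integer(n_pairs_per_mode)
    if (!all(names(n_pairs_per_mode) %in% modes))
        stop("unknown mode in n_pairs_per_mode")
    cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
                samples_per_tissue = as.integer(samples_per_tissue),
                n_pairs_per_mode = full, bias_magnitude = bias_magnitude,
                noise_sd = noise_sd, baseline_mean = baseline_mean,
                baseline_sd = baseline_sd,
                n_background = as.integer(n_background),
                n_genes = as.integer(n_genes),
                frac_intragenic = frac_intragenic,
                frac_multi_mirna_hosts = frac_multi_mirna_hosts,
                mean_gene_length = mean_gene_length,
                host_length_factor = host_length_factor,
                gene_length_sdlog = gene_length_sdlog,
                host_coupling_rho = host_coupling_rho,
                gene_noise_sd = gene_noise_sd,
                n_true_targets = as.integer(n_true_targets),
                true_target_r = true_target_r,
                n_decoy_predictions = as.integer(n_decoy_predictions),
                n_validated = as.integer(n_validated))
    counts <- c(cfg$n_tissues, cfg$samples_per_tissue, cfg$n_pairs_per_mode,
                cfg$n_background, cfg$n_genes, cfg$n_true_targets,
                cfg$n_decoy_predictions, cfg$n_validated)
    if (any(counts < 0)) stop("all counts must be >= 0")
    if (abs(cfg$host_coupling_rho) > 1 || abs(cfg$true_target_r) > 1)
        stop("correlations must lie in [-1, 1]")
    if (cfg$noise_sd < 0 || cfg$gene_noise_sd < 0)
        stop("noise sds must be >= 0")
    if (cfg$frac_intragenic < 0 || cfg$frac_intragenic > 1 ||
        cfg$frac_multi_mirna_hosts < 0 || cfg$frac_multi_mirna_hosts > 1)
        stop("fractions must lie in [0, 1]")
    if (cfg$n_validated > cfg$n_true_targets)
        stop("n_validated cannot exceed n_true_targets")
    class(cfg) <- "SimulationConfig"
    cfg
}

# three deterministic sub-seeds (annotation / miRNA expression / genes+targets)
# so that changing one stage's draws does not perturb the others
.simSeeds <- function(seed) {
    set.seed(seed)
    sample.int(2147483646L, 3)
}

.modeClass <- c(fixed_bias = "C", tissue_flip = "C",
                concurrent_comparable = "C", alternative = "A",
                silent = "NOT_EXPRESSED")

#' Simulate genomic annotation with known ground truth
#'
#' Lays `n_genes` genes (log-normal length mixture: host genes drawn
#' `host_length_factor` times longer on average) along one chromosome with
#' intergenic gaps, then places hairpins: the intragenic fraction fully
#' inside a host gene on the same strand, the rest in the gaps.  Sister-pair
#' hairpins carry two disjoint matures (one per arm), background hairpins a
#' single mature.  A configured fraction of host genes receives two hairpins.
#'
#' @param config A [simulationConfig()].
#' @return list with `annotation` (a [MirnaAnnotation-class], arms assigned)
#'   and `truth` (pair modes, hairpin/mature host mapping, host gene ids).
#' @export
simulateAnnotation <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(.simSeeds(config$seed)[1])
    n_pairs <- sum(config$n_pairs_per_mode)
    n_hp <- n_pairs + config$n_background
    n_intra <- round(config$frac_intragenic * n_hp)
    n_hosts <- round(n_intra / (1 + config$frac_multi_mirna_hosts))
    n_multi <- n_intra - n_hosts
    if (n_hosts > config$n_genes)
        stop("infeasible placement: more host genes needed than n_genes")
    sdlog <- config$gene_length_sdlog
    gene_len <- round(stats::rlnorm(
        config$n_genes, log(config$mean_gene_length) - sdlog^2 / 2, sdlog))
    host_idx <- if (n_hosts) sample.int(config$n_genes, n_hosts) else
        integer()
    gene_len[host_idx] <- round(stats::rlnorm(
        n_hosts,
        log(config$mean_gene_length * config$host_length_factor) -
            sdlog^2 / 2, sdlog))
    gene_len <- pmax(gene_len, 1000L)
    gaps <- round(stats::runif(config$n_genes + 1, 3000, 9000))
    gstart <- cumsum(gaps[seq_len(config$n_genes)] +
                     c(0, gene_len[-config$n_genes])) + 1
    gend <- gstart + gene_len - 1
    gene_id <- sprintf("GENE%04d", seq_len(config$n_genes))
    genes <- GRanges("chrS", IRanges(gstart, gend),
                     strand = sample(c("+", "-"), config$n_genes,
                                     replace = TRUE))
    names(genes) <- gene_id
    genes$biotype <- "protein_coding"

    hp_id <- sprintf("hp-%04d", seq_len(n_hp))
    modes <- rep(names(config$n_pairs_per_mode), config$n_pairs_per_mode)
    kind <- c(modes, rep("background", config$n_background))
    intra_flag <- rep(FALSE, n_hp)
    if (n_intra) intra_flag[sample.int(n_hp, n_intra)] <- TRUE
    # slots inside host genes: each host once, multi hosts twice (half each)
    multi_hosts <- if (n_multi) sample(host_idx, n_multi) else integer()
    slot_gene <- c(host_idx, multi_hosts)
    slot_part <- c(ifelse(host_idx %in% multi_hosts, 1L, 0L),
                   rep(2L, n_multi))
    slot_ord <- sample(length(slot_gene))
    slot_gene <- slot_gene[slot_ord]; slot_part <- slot_part[slot_ord]
    if (length(slot_gene) != n_intra)
        stop("internal slot bookkeeping error")

    hlen <- sample(70:110, n_hp, replace = TRUE)
    hstart <- integer(n_hp); hstrand <- character(n_hp)
    host_of <- rep(NA_character_, n_hp)
    slot_i <- 1L
    gap_start <- c(1, gend + 1)
    gap_end <- c(gstart - 1, gstart[1] + sum(gene_len) + sum(gaps))
    for (i in seq_len(n_hp)) {
        if (intra_flag[i]) {
            gi <- slot_gene[slot_i]; part <- slot_part[slot_i]
            slot_i <- slot_i + 1L
            lo <- gstart[gi]; hi <- gend[gi] - hlen[i]
            mid <- floor((gstart[gi] + gend[gi]) / 2)
            if (part == 1L) hi <- mid - hlen[i] - 1
            if (part == 2L) lo <- mid + 1
            hstart[i] <- if (hi > lo) sample(lo:hi, 1) else lo
            hstrand[i] <- as.character(strand(genes)[gi])
            host_of[i] <- gene_id[gi]
        } else {
            gpi <- sample.int(length(gap_start), 1)
            lo <- gap_start[gpi] + 100
            hi <- gap_end[gpi] - hlen[i] - 100
            hstart[i] <- if (hi > lo) sample(lo:hi, 1) else lo
            hstrand[i] <- sample(c("+", "-"), 1)
        }
    }
    hairpins <- GRanges("chrS", IRanges(hstart, hstart + hlen - 1),
                        strand = hstrand)
    names(hairpins) <- hp_id

    mat_id <- character(); mat_start <- integer(); mat_end <- integer()
    mat_strand <- character(); mat_hp <- character()
    base <- sprintf("sim-mir-%04d", seq_len(n_hp))
    for (i in seq_len(n_hp)) {
        hs <- hstart[i]; he <- hstart[i] + hlen[i] - 1
        left <- c(hs + 3, hs + 24)
        right <- c(he - 24, he - 3)
        plus <- hstrand[i] == "+"
        if (kind[i] != "background") {
            arm_left <- if (plus) "5p" else "3p"
            arm_right <- if (plus) "3p" else "5p"
            mat_id <- c(mat_id, paste0(base[i], "-", arm_left),
                        paste0(base[i], "-", arm_right))
            mat_start <- c(mat_start, left[1], right[1])
            mat_end <- c(mat_end, left[2], right[2])
            mat_strand <- c(mat_strand, hstrand[i], hstrand[i])
            mat_hp <- c(mat_hp, hp_id[i], hp_id[i])
        } else {
            side <- sample(c("left", "right"), 1)
            w <- if (side == "left") left else right
            arm <- if ((side == "left") == plus) "5p" else "3p"
            mat_id <- c(mat_id, paste0(base[i], "-", arm))
            mat_start <- c(mat_start, w[1]); mat_end <- c(mat_end, w[2])
            mat_strand <- c(mat_strand, hstrand[i])
            mat_hp <- c(mat_hp, hp_id[i])
        }
    }
    matures <- GRanges("chrS", IRanges(mat_start, mat_end),
                       strand = mat_strand)
    names(matures) <- mat_id
    matures$hairpin_id <- mat_hp
    matures$arm <- NA_character_
    ann <- assignArms(MirnaAnnotation(genes = genes, hairpins = hairpins,
                                      matures = matures))
    truth <- list(
        pair_modes = data.frame(pair_id = hp_id[kind != "background"],
                                mode = kind[kind != "background"],
                                stringsAsFactors = FALSE),
        hairpin_kind = stats::setNames(kind, hp_id),
        hairpin_host = stats::setNames(host_of, hp_id),
        mature_host = stats::setNames(host_of[match(mat_hp, hp_id)], mat_id),
        host_gene_ids = unique(host_of[!is.na(host_of)]))
    list(annotation = ann, truth = truth)
}

#' Simulate mature-miRNA expression with planted strand-selection modes
#'
#' Arm intensities are drawn on the log2 scale per the pair's mode (see
#' [simulationConfig()]), Gaussian noise `noise_sd` is added, and values are
#' exponentiated to the linear scale.  Background features get broad
#' baseline profiles.  The expression threshold is \emph{not} planted: it
#' emerges as the median of the generated matrix, exercising the
#' expression-call logic realistically.
#'
#' @param config A [simulationConfig()].
#' @param sim output of [simulateAnnotation()] run with the same config.
#' @return list with `mirna` (an [IntensityExperiment-class] with sample
#'   metadata in `colData`) and `truth` extended with `pair_class` (planted
#'   A/AC/C/NOT_EXPRESSED label per pair) and `expressed_matures`.
#' @export
simulateStrandExpression <- function(config, sim) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(.simSeeds(config$seed)[2])
    ann <- sim$annotation; truth <- sim$truth
    n_s <- config$n_tissues * config$samples_per_tissue
    tissue <- rep(seq_len(config$n_tissues),
                  each = config$samples_per_tissue)
    sample_id <- sprintf("T%d_S%02d", tissue,
                         rep(seq_len(config$samples_per_tissue),
                             config$n_tissues))
    meta <- data.frame(sample_id = sample_id, dataset_id = "SIM",
                       tissue = paste0("tissue", tissue),
                       condition = rep_len(c("normal", "disease"), n_s),
                       stringsAsFactors = FALSE)
    hi <- config$baseline_mean + 3 * config$baseline_sd
    lo <- config$baseline_mean - 3 * config$baseline_sd
    b2 <- config$bias_magnitude / 2
    m <- annotatedMatures(ann)
    feat <- names(m)
    vals <- matrix(NA_real_, length(feat), n_s,
                   dimnames = list(feat, sample_id))
    tissue_sign <- rep_len(c(1, -1), config$n_tissues)[tissue]
    expressed <- character()
    for (hid in names(annotatedHairpins(ann))) {
        kind <- truth$hairpin_kind[[hid]]
        mm <- m[m$hairpin_id == hid]
        if (kind == "background") {
            bf <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
            vals[names(mm), ] <- bf + stats::rnorm(n_s, 0, 0.5)
            next
        }
        id5 <- names(mm)[mm$arm == "5p"]; id3 <- names(mm)[mm$arm == "3p"]
        s <- sample(c(1, -1), 1)
        mu <- switch(kind,
            fixed_bias = list(m5 = rep(hi + s * b2, n_s),
                              m3 = rep(hi - s * b2, n_s)),
            tissue_flip = list(m5 = hi + s * tissue_sign * b2,
                               m3 = hi - s * tissue_sign * b2),
            concurrent_comparable = list(m5 = rep(hi + s * 0.25, n_s),
                                         m3 = rep(hi - s * 0.25, n_s)),
            alternative = if (s > 0) list(m5 = rep(hi, n_s),
                                          m3 = rep(lo, n_s))
                          else list(m5 = rep(lo, n_s), m3 = rep(hi, n_s)),
            silent = list(m5 = rep(lo, n_s), m3 = rep(lo, n_s)))
        vals[id5, ] <- mu$m5 + stats::rnorm(n_s, 0, config$noise_sd)
        vals[id3, ] <- mu$m3 + stats::rnorm(n_s, 0, config$noise_sd)
        if (kind != "silent") {
            exp_arms <- c(id5, id3)
            if (kind == "alternative")
                exp_arms <- if (s > 0) id5 else id3
            expressed <- c(expressed, exp_arms)
        }
    }
    truth$pair_class <- data.frame(
        pair_id = truth$pair_modes$pair_id,
        mode = truth$pair_modes$mode,
        class = unname(.modeClass[truth$pair_modes$mode]),
        stringsAsFactors = FALSE)
    truth$expressed_matures <- expressed
    list(mirna = IntensityExperiment(2^vals, sampleData = meta),
         truth = truth)
}

#' Simulate gene expression, host coupling and target relations
#'
#' Gene profiles are drawn on the log2 scale and exponentiated.  Host genes
#' are coupled to the reference mature of their hairpin (the 5p arm when
#' present) with Pearson correlation `host_coupling_rho` via a Gaussian
#' copula; at \eqn{\rho = 1} the host profile is an exact log2 translate of
#' the miRNA profile so the linear-scale correlation is exactly 1.  Planted
#' true-target genes are coupled to a sampled expressed regulator at
#' `true_target_r` (negative); decoy predictions link random miRNA-gene
#' pairs with independent profiles.  The validated set is a uniform sample
#' of the true relations.
#'
#' @param config A [simulationConfig()].
#' @param sim output of [simulateStrandExpression()] combined with the
#'   annotation, i.e. a list with `annotation`, `truth`, `mirna` fields.
#' @return list with `genes` (an [IntensityExperiment-class]),
#'   `predictions`, `validated` (relation `data.frame`s) and `truth`
#'   extended with `relations` (`type` = true/decoy).
#' @export
simulateHostAndTargets <- function(config, sim) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(.simSeeds(config$seed)[3])
    ann <- sim$annotation; truth <- sim$truth
    vm <- log2(intensities(sim$mirna))
    n_s <- ncol(vm)
    gene_ids <- names(annotatedGenes(ann))
    n_g <- length(gene_ids)
    gf <- stats::rnorm(n_g, config$baseline_mean, config$baseline_sd)
    vg <- gf + matrix(stats::rnorm(n_g * n_s, 0, config$gene_noise_sd),
                      n_g, n_s)
    dimnames(vg) <- list(gene_ids, colnames(vm))

    couple <- function(base_level, ref_profile, rho) {
        if (abs(rho) == 1)
            return(base_level + sign(rho) * (ref_profile -
                                             mean(ref_profile)))
        eps <- stats::rnorm(n_s)
        sdr <- stats::sd(ref_profile)
        z <- if (sdr > 0) (ref_profile - mean(ref_profile)) / sdr else
            rep(0, n_s)
        base_level + config$gene_noise_sd *
            (rho * z + sqrt(1 - rho^2) * eps)
    }

    m <- annotatedMatures(ann)
    host_map <- truth$hairpin_host
    coupled <- names(host_map)[!is.na(host_map)]
    # a multi-hairpin host gene has one profile: couple it once, to its
    # first hairpin's reference mature
    coupled <- coupled[!duplicated(host_map[coupled])]
    ref_of <- vapply(coupled, function(hid) {
        mm <- m[m$hairpin_id == hid]
        if ("5p" %in% mm$arm) names(mm)[mm$arm == "5p"][1] else names(mm)[1]
    }, "")
    for (i in seq_along(coupled)) {
        g <- host_map[[coupled[i]]]
        vg[g, ] <- couple(gf[match(g, gene_ids)], vm[ref_of[i], ],
                          config$host_coupling_rho)
    }
    truth$host_reference <- data.frame(
        hairpin_id = coupled, mature_id = unname(ref_of),
        host_gene_id = unname(host_map[coupled]),
        stringsAsFactors = FALSE)

    true_rel <- data.frame(mirna_id = character(), gene_id = character())
    if (config$n_true_targets > 0) {
        pool <- truth$expressed_matures
        if (!length(pool))
            stop("no expressed mature miRNAs to anchor true targets")
        host_ids <- truth$host_gene_ids
        free_genes <- setdiff(gene_ids, host_ids)
        if (length(free_genes) < config$n_true_targets)
            stop("not enough non-host genes for the true targets")
        regs <- sample(pool, config$n_true_targets, replace = TRUE)
        tars <- sample(free_genes, config$n_true_targets)
        for (i in seq_len(config$n_true_targets)) {
            vg[tars[i], ] <- couple(gf[match(tars[i], gene_ids)],
                                    vm[regs[i], ], config$true_target_r)
        }
        true_rel <- data.frame(mirna_id = regs, gene_id = tars,
                               stringsAsFactors = FALSE)
    }
    decoys <- data.frame(mirna_id = character(), gene_id = character())
    if (config$n_decoy_predictions > 0) {
        n_m <- nrow(vm)
        grid <- n_m * n_g
        want <- config$n_decoy_predictions
        taken <- paste(true_rel$mirna_id, true_rel$gene_id, sep = "\r")
        idx <- sample.int(grid, min(grid, want * 2 + 100))
        cand <- data.frame(mirna_id = rownames(vm)[(idx - 1) %% n_m + 1],
                           gene_id = gene_ids[(idx - 1) %/% n_m + 1],
                           stringsAsFactors = FALSE)
        cand <- cand[!(paste(cand$mirna_id, cand$gene_id, sep = "\r") %in%
                           taken), , drop = FALSE]
        if (nrow(cand) < want)
            stop("could not draw enough distinct decoy predictions")
        decoys <- cand[seq_len(want), , drop = FALSE]
    }
    predictions <- normalizeRelations(rbind(true_rel, decoys))
    validated <- if (config$n_validated > 0) {
        normalizeRelations(
            true_rel[sample.int(nrow(true_rel), config$n_validated), ,
                     drop = FALSE])
    } else true_rel
    truth$relations <- rbind(
        if (nrow(true_rel)) data.frame(true_rel, type = "true") else NULL,
        if (nrow(decoys)) data.frame(decoys, type = "decoy") else NULL)
    list(genes = IntensityExperiment(2^vg,
                                     sampleData = as.data.frame(
                                         colData(sim$mirna))),
         predictions = predictions, validated = validated, truth = truth)
}

#' Run the full generator, optionally writing the files
#'
#' Convenience wrapper chaining [simulateAnnotation()],
#' [simulateStrandExpression()] and [simulateHostAndTargets()].  With `dir`
#' set, writes `genome.gff3`, `mirna.tsv`, `genes.tsv`, `meta.tsv`,
#' `predictions.tsv`, `validated.tsv` and `truth.json`; identical config and
#' seed yield byte-identical files.  Downstream analyses consume only the
#' files / returned data objects; `truth` exists for tests.
#'
#' @param config A [simulationConfig()].
#' @param dir optional output directory.
#' @return Invisible list with `annotation`, `mirna`, `genes`,
#'   `predictions`, `validated`, `truth`, `config`.
#' @export
simulateDataset <- function(config = simulationConfig(), dir = NULL) {
    s1 <- simulateAnnotation(config)
    s2 <- simulateStrandExpression(config, s1)
    s2$annotation <- s1$annotation
    s3 <- simulateHostAndTargets(config, s2)
    out <- list(annotation = s1$annotation, mirna = s2$mirna,
                genes = s3$genes, predictions = s3$predictions,
                validated = s3$validated, truth = s3$truth, config = config)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeMirnaAnnotation(out$annotation, file.path(dir, "genome.gff3"))
        writeExpressionMatrix(out$mirna, file.path(dir, "mirna.tsv"))
        writeExpressionMatrix(out$genes, file.path(dir, "genes.tsv"))
        utils::write.table(as.data.frame(colData(out$mirna)),
                           file.path(dir, "meta.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(out$predictions,
                           file.path(dir, "predictions.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(out$validated, file.path(dir, "validated.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(out)
}
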