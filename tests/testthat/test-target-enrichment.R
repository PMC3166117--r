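test_that("shannon entropy matches closed forms", {
    expect_equal(shannonEntropy(rep(1, 4)), 2)
    expect_equal(shannonEntropy(c(0, 0, 5, 0)), 0)
    expect_equal(shannonEntropy(c(1, 1, 2)), 1.5)
    expect_error(shannonEntropy(c(0, 0)), "all-zero")
    expect_error(shannonEntropy(c(-1, 2)), "non-negative")
})

test_that("regulator filtering removes the union of the two quantiles", {
    # 8 features: two flagged by both criteria -> 6 retained
    v <- rbind(2^outer(rep(8, 6), rnorm(10, 0, 0.01), "+"),
               spiky1 = c(100, rep(0.001, 9)),
               spiky2 = c(rep(0.001, 9), 100))
    rownames(v)[1:6] <- paste0("flat", 1:6)
    v["spiky1", ] <- v["spiky1", ] / 50   # also lowest mean
    v["spiky2", ] <- v["spiky2", ] / 50
    kept <- filterMirnas(v, 0.25, 0.25)
    expect_setequal(kept, paste0("flat", 1:6))

    # disjoint flagged sets of 2 each -> 4 retained
    v2 <- rbind(hiflat1 = rep(1000, 10), hiflat2 = rep(1100, 10),
                hispiky1 = c(1e6, rep(1, 9)), hispiky2 = c(rep(1, 9), 1e6),
                loflat1 = rep(0.01, 10), loflat2 = rep(0.011, 10),
                hiflat3 = rep(1200, 10), hiflat4 = rep(1300, 10))
    kept2 <- filterMirnas(v2, 0.25, 0.25)
    expect_setequal(kept2, c("hiflat1", "hiflat2", "hiflat3", "hiflat4"))

    # zero quantiles retain everything
    expect_setequal(filterMirnas(v2, 0, 0), rownames(v2))
})

test_that("percentile selection takes the most negative of the background", {
    scored <- data.frame(mirna_id = paste0("m", 1:5),
                         gene_id = paste0("G", 1:5),
                         r = c(-0.9, -0.5, -0.4, -0.1, 0.3), mode = "REAL")
    sel <- selectSupported(scored, 40)  # background 4, ceil(1.6) = 2
    expect_equal(sel$r, c(-0.9, -0.5))
    expect_equal(nrow(selectSupported(scored, 100)), 4)
    expect_equal(selectSupported(scored, 100)$r,
                 sort(scored$r[scored$r < 0]))
    pos <- scored[scored$r > 0, ]
    expect_error(selectSupported(pos, 10), "empty background")
})

test_that("enrichment score is observed over proportional expectation", {
    bg <- data.frame(mirna_id = sprintf("m%03d", 1:100),
                     gene_id = sprintf("G%03d", 1:100), r = -runif(100))
    validated <- bg[1:10, c("mirna_id", "gene_id")]
    # selected 10 containing 5 validated -> expected 1, score 5
    sel <- bg[c(1:5, 60:64), ]
    es <- enrichmentScore(sel, bg, validated)
    expect_equal(es$expected, 1)
    expect_equal(es$score, 5)
    # full background -> score exactly 1
    expect_equal(enrichmentScore(bg, bg, validated)$score, 1)
    # no validated in selection -> score 0
    expect_equal(enrichmentScore(bg[50:59, ], bg, validated)$score, 0)
    expect_error(enrichmentScore(sel, bg, data.frame(mirna_id = "zz",
                                                     gene_id = "QQ")),
                 "no validated relation in the background")
})

test_that("expected counts are conserved over a partition of background", {
    set.seed(12)
    bg <- data.frame(mirna_id = sprintf("m%03d", 1:90),
                     gene_id = sprintf("G%03d", 1:90), r = -runif(90))
    validated <- bg[sample(90, 12), c("mirna_id", "gene_id")]
    parts <- split(seq_len(90), rep(1:3, each = 30))
    exp_sum <- sum(vapply(parts, function(idx)
        enrichmentScore(bg[idx, ], bg, validated)$expected, 0))
    expect_equal(exp_sum, 12)
    # invariance under relabeling of non-validated relations
    bg2 <- bg
    nonval <- !(paste(bg2$mirna_id, bg2$gene_id) %in%
                    paste(validated$mirna_id, validated$gene_id))
    bg2$gene_id[nonval] <- paste0("X", seq_len(sum(nonval)))
    expect_equal(enrichmentScore(bg2[1:30, ], bg2, validated)$observed,
                 enrichmentScore(bg[1:30, ], bg, validated)$observed)
})

test_that("relation scoring excludes filtered regulators and proxy selves", {
    set.seed(6)
    n <- 12
    vm <- rbind("mir-1" = 2^rnorm(n, 8, 1), "mir-2" = 2^rnorm(n, 8, 1))
    colnames(vm) <- paste0("s", 1:n)
    vg <- rbind(HOST1 = 2^rnorm(n, 8, 1), T1 = 2^rnorm(n, 8, 1),
                T2 = 2^rnorm(n, 8, 1))
    vg["T1", ] <- max(vm["mir-1", ]) + 10 - vm["mir-1", ]  # anti-linear
    colnames(vg) <- paste0("s", 1:n)
    preds <- data.frame(mirna_id = c("mir-1", "mir-1", "mir-2"),
                        gene_id = c("T1", "HOST1", "T2"))
    mirna <- IntensityExperiment(vm); genes <- IntensityExperiment(vg)
    sc <- scoreRelations(mirna, genes, preds, mode = "REAL",
                         entropy_q = 0, mean_q = 0)
    expect_equal(nrow(sc), 3)
    expect_equal(sc$r[sc$gene_id == "T1"], -1)

    # PROXY: mir-1 is hosted by HOST1; its self-relation is excluded and
    # mir-2 (no host) cannot be scored
    pm <- data.frame(mature_id = "mir-1", host_gene_id = "HOST1")
    expect_message(
        expect_message(
            scp <- scoreRelations(mirna, genes, preds, mode = "PROXY",
                                  proxyMap = pm, entropy_q = 0,
                                  mean_q = 0),
            "self-targeting"),
        "not scorable")
    expect_equal(nrow(scp), 1)
    expect_equal(scp$gene_id, "T1")
    expect_equal(scp$r, cor(vg["HOST1", ], vg["T1", ]))

    # a prediction naming a filtered-out regulator disappears
    vm2 <- rbind(vm, "mir-weak" = rep(0.01, n))
    preds2 <- rbind(preds, data.frame(mirna_id = "mir-weak",
                                      gene_id = "T2"))
    sc2 <- suppressMessages(
        scoreRelations(IntensityExperiment(vm2), genes, preds2,
                       mode = "REAL", entropy_q = 0, mean_q = 1 / 3))
    expect_false("mir-weak" %in% sc2$mirna_id)
})

test_that("REAL enrichment finds planted targets while PROXY stays null", {
    cfg <- simulationConfig(
        seed = 42,
        n_pairs_per_mode = c(fixed_bias = 20, concurrent_comparable = 20,
                             alternative = 20),
        n_background = 100, samples_per_tissue = 20, n_genes = 600,
        frac_intragenic = 1, host_coupling_rho = 0,
        n_true_targets = 150, true_target_r = -0.7,
        n_decoy_predictions = 2000, n_validated = 40)
    sim <- simulateDataset(cfg)
    res <- suppressMessages(runRealVsProxy(
        sim$mirna, sim$genes, sim$annotation, sim$predictions,
        sim$validated, cutoffs = c(5, 100), entropy_q = 0, mean_q = 0))
    expect_gt(res$real$score[res$real$cutoff == 5], 2)
    expect_equal(res$real$score[res$real$cutoff == 100], 1)
    expect_equal(res$proxy$score[res$proxy$cutoff == 100], 1)
    # PROXY detects (almost) nothing the REAL analysis detects at 5%
    expect_lte(res$overlap$jaccard[res$overlap$cutoff == 5], 0.1)

    # planted anti-correlation is realized
    truth <- sim$truth$relations
    true_keys <- paste(truth$mirna_id[truth$type == "true"],
                       truth$gene_id[truth$type == "true"])
    sc <- suppressMessages(scoreRelations(sim$mirna, sim$genes,
                                          sim$predictions, mode = "REAL",
                                          entropy_q = 0, mean_q = 0))
    r_true <- sc$r[paste(sc$mirna_id, sc$gene_id) %in% true_keys]
    expect_lt(abs(mean(r_true) - (-0.7)), 0.1)
})

test_that("full miRNA-host coupling makes REAL and PROXY curves agree", {
    cfg <- simulationConfig(
        seed = 9,
        n_pairs_per_mode = c(tissue_flip = 30, fixed_bias = 30),
        n_background = 60, samples_per_tissue = 20, n_genes = 500,
        frac_intragenic = 1, host_coupling_rho = 1,
        n_true_targets = 120, true_target_r = -0.7,
        n_decoy_predictions = 1500, n_validated = 40)
    sim <- simulateDataset(cfg)
    res <- suppressMessages(runRealVsProxy(
        sim$mirna, sim$genes, sim$annotation, sim$predictions,
        sim$validated, cutoffs = c(5, 25, 100),
        entropy_q = 0, mean_q = 0))
    for (cc in c(5, 25)) {
        sr <- res$real$score[res$real$cutoff == cc]
        sp <- res$proxy$score[res$proxy$cutoff == cc]
        expect_gt(sp, 1)              # proxy now carries real signal
        expect_lt(abs(sr - sp) / sr, 0.6)  # same order, sampling noise apart
    }
    expect_error(
        suppressMessages(runRealVsProxy(
            sim$mirna, sim$genes, sim$annotation, sim$predictions,
            sim$validated[0, ], cutoffs = 5)),
        "empty validated")
})
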