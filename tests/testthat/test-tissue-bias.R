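test_that("tau matches its formula and limiting cases", {
    x <- rbind(uniform = c(3, 3, 3, 3),
               single  = c(5, 0, 0, 0),
               mixed   = c(8, 2, 0, 0))
    colnames(x) <- c("AG", "testis", "head", "gut")
    tt <- computeTau(x)
    expect_equal(tt$tau[tt$gene_id == "uniform"], 0)
    expect_equal(tt$tau[tt$gene_id == "single"], 1)
    expect_equal(tt$tau[tt$gene_id == "mixed"], (0 + 0.75 + 1 + 1) / 3)
    expect_identical(tt$argmax_tissue, c("AG", "AG", "AG"))
    expect_error(computeTau(x[, 1, drop = FALSE]), "at least 2 tissues")
    ## zero-expression genes are flagged undefined
    z <- computeTau(rbind(c(0, 0), c(1, 0)))
    expect_true(is.na(z$tau[1]))
})

test_that("tau is scale invariant and monotone in the dominant tissue", {
    set.seed(3)
    for (i in 1:10) {
        x <- matrix(rexp(4), 1)
        colnames(x) <- paste0("t", 1:4)
        expect_equal(computeTau(x)$tau, computeTau(x * 7.3)$tau)
        xmax <- max.col(x)
        x2 <- x; x2[xmax] <- x2[xmax] * 1.5
        expect_gte(computeTau(x2)$tau, computeTau(x)$tau)
    }
})

make_bias_tables <- function(n = 200, seed = 11) {
    set.seed(seed)
    ids <- paste0("g", 1:n)
    organ <- data.frame(gene_id = ids,
                        log_fc = runif(n, -6, 2),
                        ave_expr = runif(n, -1, 6),
                        p_adj = runif(n)^2,
                        stringsAsFactors = FALSE)
    other <- data.frame(gene_id = ids,
                        log_fc = runif(n, -2, 3),
                        stringsAsFactors = FALSE)
    tpm <- setNames(runif(n, 0, 50), ids)
    list(organ = organ, other = other, tpm = tpm)
}

test_that("the bias classifier applies every criterion jointly", {
    organ <- data.frame(gene_id = c("g1", "g2"),
                        log_fc = c(-4.0, -4.0),
                        ave_expr = c(0.5, 0.5),
                        p_adj = c(0.001, 0.001))
    other <- data.frame(gene_id = c("g1", "g2"), log_fc = c(1.2, 1.2))
    tpm <- c(g1 = 2, g2 = 0.5)
    th <- biasThresholds("AG")
    ## g1 passes all five criteria; g2 fails only the TPM minimum
    expect_identical(classifyTissueBias(organ, other, tpm, th), "g1")
    expect_error(classifyTissueBias(organ, other[1, , drop = FALSE],
                                    tpm, th), "same gene universe")
})

test_that("the classifier equals a brute-force row filter", {
    tabs <- make_bias_tables()
    th <- biasThresholds("testis")
    got <- classifyTissueBias(tabs$organ, tabs$other, tabs$tpm, th)
    brute <- tabs$organ$gene_id[
        tabs$organ$log_fc <= -0.46 & tabs$organ$p_adj <= 0.01 &
        tabs$tpm >= 5 & tabs$organ$ave_expr >= 0 &
        tabs$other$log_fc >= 1]
    expect_identical(got, brute)
})

test_that("relaxing any single threshold yields a superset", {
    tabs <- make_bias_tables(seed = 13)
    base <- biasThresholds("AG")
    sel0 <- classifyTissueBias(tabs$organ, tabs$other, tabs$tpm, base)
    relaxed <- list(
        biasThresholds("AG", logfc_organ_vs_whole = -1),
        biasThresholds("AG", p_adj_max = 0.5),
        biasThresholds("AG", min_tpm = 0),
        biasThresholds("AG", other_organ_logfc_min = -5),
        biasThresholds("AG", ave_expr_strict = FALSE))
    for (th in relaxed)
        expect_true(all(sel0 %in% classifyTissueBias(tabs$organ,
                                                     tabs$other,
                                                     tabs$tpm, th)))
})

test_that("calibration recovers planted organ-specific genes", {
    set.seed(21)
    n <- 400
    ids <- paste0("g", 1:n)
    biased <- ids[1:60]
    ## multi-tissue reference on log2(TPM+1): planted genes express in the
    ## organ only, background genes everywhere
    ref <- matrix(runif(n * 4, 2, 6), n,
                  dimnames = list(ids, c("AG", "testis", "head", "gut")))
    ref[1:60, c("testis", "head", "gut")] <- runif(60 * 3, 0, 0.1)
    tau <- computeTau(ref)
    tauSet <- tau$gene_id[tau$tau >= 0.9 & tau$argmax_tissue == "AG"]
    expect_true(all(biased %in% tauSet))
    ## organ-vs-whole contrasts consistent with the same truth, plus noise
    organ <- data.frame(gene_id = ids,
                        log_fc = ifelse(ids %in% biased,
                                        rnorm(n, -5, 0.4),
                                        rnorm(n, 0, 0.8)),
                        ave_expr = runif(n, 0.5, 5),
                        p_adj = ifelse(ids %in% biased,
                                       1e-6, runif(n)))
    other <- data.frame(gene_id = ids,
                        log_fc = ifelse(ids %in% biased, 2, 0))
    tpm <- setNames(ifelse(ids %in% biased, 30, 10), ids)
    grid <- list(logfc_organ_vs_whole = c(-5, -3.59, -2, -1),
                 min_tpm = c(1, 5, 20))
    th <- calibrateThresholds(tauSet, organ, other, tpm, grid, "AG")
    sel <- classifyTissueBias(organ, other, tpm, th)
    expect_gte(length(intersect(sel, tauSet)) / length(tauSet), 0.8)
    ## idempotence: re-applying the selected thresholds reproduces the set
    expect_identical(classifyTissueBias(organ, other, tpm, th), sel)
    expect_error(calibrateThresholds(character(0), organ, other, tpm,
                                     grid), "empty")
})

test_that("a grid cell reproducing the tau set exactly is selected", {
    organ <- data.frame(gene_id = paste0("g", 1:10),
                        log_fc = c(rep(-5, 4), rep(0, 6)),
                        ave_expr = 1, p_adj = 1e-4)
    other <- data.frame(gene_id = paste0("g", 1:10), log_fc = 2)
    tpm <- setNames(rep(10, 10), paste0("g", 1:10))
    tauSet <- paste0("g", 1:4)
    th <- calibrateThresholds(tauSet, organ, other, tpm,
                              list(logfc_organ_vs_whole = c(-3.59, -1)),
                              "AG")
    expect_equal(attr(th, "jaccard"), 1)
    expect_setequal(classifyTissueBias(organ, other, tpm, th), tauSet)
})
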