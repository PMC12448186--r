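pair_map <- function(n, A = "A", B = "B") {
    OrthologMap(setNames(data.frame(paste0("a", 1:n), paste0("b", 1:n),
                                    stringsAsFactors = FALSE), c(A, B)))
}

test_that("ortholog restriction keeps rows expressed in every species", {
    map <- pair_map(3)
    deA <- toy_de_table(paste0("a", 1:3), c(1, -1, 2), c(0.01, 0.5, 0.05))
    deB <- toy_de_table(paste0("b", 1:3), c(2, -3, -1), c(0.02, 0.9, 0.2))
    j <- restrictToOrthologs(list(A = deA, B = deB), map)
    expect_identical(nrow(j), 3L)
    ## an ortholog expressed in one species only is dropped
    j2 <- restrictToOrthologs(list(A = deA[1:2, ], B = deB), map)
    expect_identical(nrow(j2), 2L)
    expect_error(restrictToOrthologs(list(A = deA), map),
                 "species missing")
})

test_that("joined rows equal a brute-force intersection on simulation", {
    sim <- simulateDataset(small_config(n_genes = 300, seed = 17))
    deA <- latitudinalDE(sim$counts$A, "A", "AG")
    deB <- latitudinalDE(sim$counts$B, "B", "AG")
    j <- restrictToOrthologs(list(A = deA, B = deB), sim$orthologs)
    tab <- orthologTable(sim$orthologs)
    brute <- sum(tab$A %in% deA$gene_id & tab$B %in% deB$gene_id)
    expect_identical(nrow(j), brute)
    cnt <- sharedDECounts(j)
    bruteShared <- sum(tab$A %in% deA$gene_id[deA$is_de] &
                       tab$B %in% deB$gene_id[deB$is_de])
    expect_identical(cnt$k_obs, bruteShared)
})

test_that("shared counts cover the degenerate extremes", {
    map <- pair_map(4)
    none <- toy_de_table(paste0("a", 1:4), 1:4, rep(0.9, 4))
    noneB <- toy_de_table(paste0("b", 1:4), 1:4, rep(0.9, 4))
    all_ <- toy_de_table(paste0("a", 1:4), 1:4, rep(0.001, 4))
    allB <- toy_de_table(paste0("b", 1:4), 1:4, rep(0.001, 4))
    expect_identical(sharedDECounts(restrictToOrthologs(
        list(A = none, B = noneB), map))$k_obs, 0L)
    cnt <- sharedDECounts(restrictToOrthologs(
        list(A = all_, B = allB), map))
    expect_identical(cnt$k_obs, cnt$N)
})

test_that("the expected shared count is the independence product", {
    expect_equal(expectedShared(c(10, 20), 100), 2)
    expect_equal(expectedShared(c(50, 50), 50), 50)  # saturation
    expect_equal(expectedShared(c(10, 20, 30), 100), 10 * 20 * 30 / 100^2)
    expect_error(expectedShared(c(10, 20), 0), "positive")
    ## permutation-null mean over label shuffles
    set.seed(5)
    for (i in 1:3) {
        N <- 200
        de1 <- seq_len(N) %in% sample(N, 40)
        de2 <- seq_len(N) %in% sample(N, 70)
        B <- 20000
        permMean <- perm_shared_oracle(de1, de2, B = B, seed = i)
        E <- expectedShared(c(40, 70), N)
        se <- sd(replicate(200, sum(sample(de1) & de2))) / sqrt(B)
        expect_lt(abs(permMean - E), 3 * max(se, 0.05))
    }
})

test_that("the enrichment test is an exact upper binomial tail", {
    expect_equal(sharedDEEnrichmentTest(0, c(10, 10), 100), 1)
    expect_equal(sharedDEEnrichmentTest(5, c(10, 10), 100),
                 sum(dbinom(5:100, 100, 0.01)), tolerance = 1e-12)
    p <- vapply(0:20, function(k)
        sharedDEEnrichmentTest(k, c(30, 40), 200), 0)
    expect_true(all(diff(p) < 0))
    expect_error(sharedDEEnrichmentTest(5, c(300, 10), 200), "invalid")
})

test_that("directionality concordance counts signs and handles ties", {
    map <- pair_map(3)
    deA <- toy_de_table(paste0("a", 1:3), c(1, -1, 1), rep(0.01, 3))
    deB <- toy_de_table(paste0("b", 1:3), c(2, -3, -1), rep(0.01, 3))
    j <- restrictToOrthologs(list(A = deA, B = deB), map)
    sc <- signConcordance(j, "shared_de")
    expect_identical(sc$k_same, 2L)
    expect_identical(sc$n, 3L)
    ## among concordant genes, one of two has the common negative sign
    expect_equal(sc$pct_higher_in_maine, 50)
    ## exact zero logFC is excluded with a warning
    deB$log_fc[3] <- 0
    j0 <- restrictToOrthologs(list(A = deA, B = deB), map)
    expect_warning(sc0 <- signConcordance(j0, "all"), "exactly 0")
    expect_identical(sc0$n, 2L)
})

test_that("the concordance test matches closed forms and is monotone", {
    expect_equal(concordanceTest(10, 10, 0.5), 2^-10)
    p <- vapply(0:10, function(k) concordanceTest(k, 10, 0.4), 0)
    expect_true(all(diff(p) < 0))
    ## k at the null expectation gives an unremarkable p
    expect_gt(concordanceTest(50, 100, 0.5), 0.4)
    expect_error(concordanceTest(5, 10, 1.2), "p0")
})

test_that("logFC correlation is a Spearman rank correlation", {
    map <- pair_map(5)
    deA <- toy_de_table(paste0("a", 1:5), c(0.1, 0.5, 1, 2, 3),
                        rep(0.5, 5))
    deB <- toy_de_table(paste0("b", 1:5), c(1, 4, 9, 16, 25), rep(0.5, 5))
    j <- restrictToOrthologs(list(A = deA, B = deB), map)
    expect_equal(logfcCorrelation(j)$rho, 1)
    deB$log_fc <- -deB$log_fc
    j2 <- restrictToOrthologs(list(A = deA, B = deB), map)
    expect_equal(logfcCorrelation(j2)$rho, -1)
    deB$log_fc <- rep(2, 5)
    j3 <- restrictToOrthologs(list(A = deA, B = deB), map)
    expect_error(logfcCorrelation(j3), "undefined correlation")
})

test_that("uncorrelated species show ~50% concordance and near-zero rho", {
    cfg <- small_config(n_genes = 4000, ortholog_coverage = 1,
                        cross_species_corr = 0, effect_sd = 0.5,
                        shared_outlier_fraction = 0, seed = 29)
    sim <- simulateDataset(cfg)
    deA <- latitudinalDE(sim$counts$A, "A", "AG")
    deB <- latitudinalDE(sim$counts$B, "B", "AG")
    rep <- parallelismReport(list(A = deA, B = deB), sim$orthologs, "AG")
    expect_gt(rep$pct_same_direction_all, 45)
    expect_lt(rep$pct_same_direction_all, 55)
    expect_lt(abs(rep$spearman_rho), 0.06)
})

test_that("the assembled report is internally consistent", {
    sim <- simulateDataset(small_config(n_genes = 500, seed = 37))
    deA <- latitudinalDE(sim$counts$A, "A", "AG")
    deB <- latitudinalDE(sim$counts$B, "B", "AG")
    rep <- parallelismReport(list(A = deA, B = deB), sim$orthologs, "AG")
    expect_lte(rep$k_obs, min(rep$n_de_each))
    expect_gte(rep$expected_shared, 0)
    expect_true(rep$spearman_rho >= -1 && rep$spearman_rho <= 1)
    expect_true(all(c(rep$pct_same_direction_all,
                      rep$pct_same_direction_shared) <= 100))
    expect_output(print(rep), "Parallelism report")
})
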