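make_cds <- function(m, lengths, pops = NULL) {
    n <- ncol(m)
    if (is.null(pops)) pops <- rep(c("Maine", "Panama"), length.out = n)
    if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(n))
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    meta <- data.frame(sample_id = colnames(m), species = "A",
                       population = pops, tissue = "AG",
                       replicate = as.integer(ave(seq_len(n), pops,
                                                  FUN = seq_along)))
    CountsDataset(m, lengths, meta)
}

test_that("TPM follows the length-normalised definition", {
    ## single gene: any nonzero count gives TPM 1e6
    cds1 <- make_cds(matrix(c(7L, 3L), 1), lengths = 1500)
    expect_equal(unname(computeTpm(cds1)), matrix(1e6, 1, 2))
    ## hand-computed two-gene case
    cds2 <- make_cds(matrix(c(10L, 10L), 2, 1), lengths = c(1000, 2000),
                     pops = "Maine")
    expect_equal(unname(computeTpm(cds2)),
                 matrix(c(2e6 / 3, 1e6 / 3), 2, 1), tolerance = 1e-9)
    ## all-zero sample stays all-zero; nonzero columns sum to 1e6
    m <- matrix(c(0L, 0L, 4L, 8L), 2)
    cds3 <- make_cds(m, lengths = c(500, 800))
    tpm <- computeTpm(cds3)
    expect_equal(unname(tpm[, 1]), c(0, 0))
    expect_equal(sum(tpm[, 2]), 1e6)
})

test_that("population medians follow the sorting definition", {
    m <- matrix(c(1L, 2L, 9L, 5L, 7L, 100L), 1)
    colnames(m) <- paste0("s", 1:6)
    cds <- make_cds(m, lengths = 1000,
                    pops = rep(c("Maine", "Panama"), each = 3))
    tpm <- counts(cds)  # single gene; use raw counts as the value matrix
    med <- medianPopulationTpm(tpm, sampleInfo(cds), "A", "AG",
                               c("Maine", "Panama"))
    expect_equal(unname(med["g1", ]), c(2, 7))
    ## even replicate count: mean of the central two, against sort()
    x <- c(3, 9, 1, 7)
    s <- sort(x)
    expect_equal(median(x), mean(s[2:3]))
    expect_error(medianPopulationTpm(tpm, sampleInfo(cds), "A", "AG",
                                     "Zambia"), "population absent")
})

test_that("the expression filter is strict and matches a recount", {
    med <- matrix(c(1.0, 0, 2, 1.0, 1.5, 0.4), 3,
                  dimnames = list(c("g1", "g2", "g3"), c("M", "P")))
    expect_identical(filterExpressed(med), c("g2", "g3"))
    ## boundary: median exactly 1 in both -> excluded
    expect_false("g1" %in% filterExpressed(med))
    sim <- simulateDataset(small_config(seed = 3))
    tpm <- computeTpm(sim$counts$A)
    med2 <- medianPopulationTpm(tpm, sampleInfo(sim$counts$A), "A", "AG",
                                c("Maine", "Panama"))
    brute <- rownames(med2)[med2[, 1] > 1 | med2[, 2] > 1]
    expect_identical(filterExpressed(med2), brute)
})

test_that("log2-CPM matches its closed form and is monotone", {
    m <- matrix(c(0L, 999999L, 1L, 1L), 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    lc <- logCpm(m, prior_count = 0.5)
    expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6),
                 tolerance = 1e-5)
    expect_equal(lc["g1", "s1"], -1, tolerance = 1e-3)
    ## monotone in count at fixed library size
    v <- log2((0:10 + 0.5) / (1e6 + 1) * 1e6)
    expect_true(all(diff(v) > 0))
    ## doubling counts and library leaves values nearly unchanged
    big <- matrix(c(1000L, 999000L), 2)
    expect_equal(logCpm(big), logCpm(big * 2L), tolerance = 1e-3)
})

test_that("BH adjustment matches the hand step-up rule", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_error(adjustBH(c(0.5, 0)), "0, 1")
    set.seed(1)
    for (i in 1:20) {
        p <- runif(sample(3:50, 1))
        adj <- adjustBH(p)
        expect_equal(adj, bh_oracle(p))
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
        ## rank order preserved up to ties
        expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
})

test_that("EB hyperparameter estimation recovers a known prior", {
    ## degenerate: identical variances -> infinite prior df
    eb <- estimateEBHyperparams(rep(0.25, 50), d_g = 4)
    expect_identical(eb$d0, Inf)
    expect_equal(eb$s0_sq, 0.25, tolerance = 0.35)
    ## recovery from the assumed hierarchy
    set.seed(99)
    s2 <- rvar_from_prior(20000, d0 = 4, s0 = 0.05, dg = 4)
    fit <- estimateEBHyperparams(s2, d_g = 4)
    expect_gt(fit$d0, 4 * 0.85)
    expect_lt(fit$d0, 4 * 1.15)
    expect_equal(fit$s0_sq, 0.05, tolerance = 0.15 * 0.05)
    ## monotonicity: larger spread of log variances -> smaller d0
    set.seed(100)
    s2a <- rvar_from_prior(5000, d0 = 50, s0 = 0.05, dg = 4)
    s2b <- rvar_from_prior(5000, d0 = 2, s0 = 0.05, dg = 4)
    expect_gt(estimateEBHyperparams(s2a, 4)$d0,
              estimateEBHyperparams(s2b, 4)$d0)
})

test_that("the moderated t collapses to the ordinary pooled t when d0 = 0", {
    set.seed(7)
    m <- matrix(rnorm(30 * 6), 30, dimnames = list(paste0("g", 1:30),
                                                   paste0("s", 1:6)))
    groups <- rep(c("Panama", "Maine"), each = 3)
    tab <- moderatedTTest(m, groups, eb = list(d0 = 0, s0_sq = 1))
    oracle <- pooled_t_oracle(m, 1:3, 4:6)
    expect_equal(tab$t_mod, unname(oracle[, "t"]), tolerance = 1e-10)
    expect_equal(tab$p_raw, unname(oracle[, "p"]), tolerance = 1e-10)
    expect_equal(tab$log_fc, unname(oracle[, "diff"]), tolerance = 1e-12)
})

test_that("moderated t handles degenerate and planted cases", {
    m <- matrix(rep(c(1, 2, 3), 4), 1, 12)
    rownames(m) <- "g1"; colnames(m) <- paste0("s", 1:12)
    groups <- rep(c("Panama", "Maine"), each = 6)
    ## identical group means -> t = 0, p = 1
    tab <- moderatedTTest(m, groups, eb = list(d0 = 0, s0_sq = 1))
    expect_equal(tab$t_mod, 0)
    expect_equal(tab$p_raw, 1)
    expect_error(moderatedTTest(m, c("Panama", rep("Maine", 11))),
                 "at least 2 samples")
    ## planted strong effect at low noise is detected
    set.seed(13)
    mm <- matrix(rnorm(50 * 6, sd = 0.1), 50)
    rownames(mm) <- paste0("g", 1:50); colnames(mm) <- paste0("s", 1:6)
    mm[1, 1:3] <- mm[1, 1:3] + 2
    tab2 <- moderatedTTest(mm, rep(c("Panama", "Maine"), each = 3))
    expect_lt(tab2$p_raw[1], 1e-4)
    expect_equal(tab2$log_fc[1], 2, tolerance = 0.3)
})

test_that("DE calling applies the adjusted-P cutoff and percent arithmetic", {
    tab <- data.frame(gene_id = paste0("g", 1:4),
                      p_raw = c(0.001, 0.02, 0.2, 0.9))
    out <- callDE(tab, alpha = 0.1)
    expect_identical(out$is_de, out$p_adj <= 0.1)
    expect_true(all(out$p_adj >= out$p_raw))
    out0 <- callDE(tab, alpha = 0)
    expect_identical(sum(out0$is_de), 0L)
    expect_equal(percentDE(798, 8023), 9.9)
    expect_equal(percentDE(1568, 7687), 20.4)
})
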