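#' Log2 counts per million
#'
#' \eqn{\log_2\!\big( (c + p) / (N + 2p) \cdot 10^6 \big)} where \eqn{N} is
#' the sample library size (column sum) and \eqn{p} a prior count that
#' stabilises low counts.
#'
#' @param object a \linkS4class{CountsDataset}, or a counts matrix.
#' @param prior_count prior count added to every observation (default 0.5).
#' @param lib_size optional per-sample library sizes; defaults to the
#'   column sums of the count matrix.
#' @return gene x sample matrix of log2-CPM values.
#' @export
logCpm <- function(object, prior_count = 0.5, lib_size = NULL) {
    if (prior_count <= 0) stop("prior_count must be > 0")
    m <- if (is(object, "CountsDataset")) counts(object) else as.matrix(object)
    if (is.null(lib_size)) lib_size <- colSums(m)
    t(log2(t(m + prior_count) / (lib_size + 2 * prior_count) * 1e6))
}

## Newton solve of trigamma(y) = x, vectorised; x > 0.
trigamma_inverse <- function(x) {
    y <- 0.5 + 1 / x
    for (iter in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (max(abs(dif / y)) < 1e-10) break
    }
    y
}

#' Empirical-Bayes hyperparameters for gene-wise variances
#'
#' Fits a scaled inverse-chi-square prior with \code{d0} prior degrees of
#' freedom and prior variance \code{s0_sq} to the gene-wise residual
#' variances by the method of moments on the log variances: \code{d0}
#' solves \eqn{\psi'(d_0/2) = \mathrm{var}(\log s^2) - \psi'(d_g/2)}
#' (clamped to \code{+Inf} when the right-hand side is non-positive, i.e.
#' the variances are no more spread than sampling alone explains), and
#' \code{s0_sq} follows from the mean of the log variances with the
#' digamma corrections.
#'
#' @param s_sq per-gene residual variances (>= 10 positive values).
#' @param d_g residual degrees of freedom (constant across genes).
#' @return list with elements \code{d0} and \code{s0_sq}, of class
#'   \code{EBHyperparams}.
#' @export
estimateEBHyperparams <- function(s_sq, d_g) {
    if (length(d_g) != 1L || d_g <= 0) stop("d_g must be a positive scalar")
    pos <- s_sq[is.finite(s_sq) & s_sq > 0]
    if (length(pos) < 10L)
        stop("need at least 10 genes with positive residual variance")
    z <- log(pos)
    ## E[log s^2] = log(sigma^2) + digamma(d/2) - log(d/2); correct to the
    ## log-variance scale before taking moments.
    e <- z - digamma(d_g / 2) + log(d_g / 2)
    evar <- var(e) - trigamma(d_g / 2)
    if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s0 <- exp(mean(e))
    } else {
        d0 <- 2 * trigamma_inverse(evar)
        s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    structure(list(d0 = d0, s0_sq = s0), class = "EBHyperparams")
}

#' Moderated t-test for a two-group latitudinal contrast
#'
#' For each gene: \code{log_fc} is the mean log2-CPM in the low-latitude
#' group minus the mean in the high-latitude group (negative = lower in
#' the low-latitude population); the pooled residual variance
#' \eqn{s_g^2} (with \eqn{d_g = n_1+n_2-2} df) is shrunk towards the
#' prior, \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, and the
#' moderated statistic \eqn{t = \mathrm{logFC} / \sqrt{\tilde s^2 (1/n_1 +
#' 1/n_2)}} is referred to a t distribution on \eqn{d_0 + d_g} degrees of
#' freedom (the normal limit when \eqn{d_0 = \infty}). With \code{d0 = 0}
#' the statistic reduces exactly to the ordinary pooled two-sample t.
#'
#' @param logcpm gene x sample matrix of log2-CPM values.
#' @param groups vector (length \code{ncol(logcpm)}) of group labels.
#' @param eb an \code{EBHyperparams} object, or \code{NULL} to estimate it
#'   from these data.
#' @param contrast length-2 character vector \code{c(low, high)}: the
#'   log fold change is computed as low minus high.
#' @return data.frame with columns \code{gene_id}, \code{log_fc},
#'   \code{ave_expr}, \code{t_mod}, \code{df_total}, \code{p_raw}.
#' @export
moderatedTTest <- function(logcpm, groups, eb = NULL,
                           contrast = c("Panama", "Maine")) {
    groups <- as.character(groups)
    if (length(groups) != ncol(logcpm))
        stop("groups must have one entry per sample column")
    low <- contrast[1]; high <- contrast[2]
    i1 <- which(groups == low); i2 <- which(groups == high)
    n1 <- length(i1); n2 <- length(i2)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples (got ", n1, " '", low,
             "', ", n2, " '", high, "')")
    m1 <- rowMeans(logcpm[, i1, drop = FALSE])
    m2 <- rowMeans(logcpm[, i2, drop = FALSE])
    ss1 <- rowSums((logcpm[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((logcpm[, i2, drop = FALSE] - m2)^2)
    dg <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / dg
    if (is.null(eb)) eb <- estimateEBHyperparams(s2, dg)
    d0 <- eb$d0
    post <- if (is.infinite(d0)) rep(eb$s0_sq, length(s2))
            else (d0 * eb$s0_sq + dg * s2) / (d0 + dg)
    se <- sqrt(post * (1 / n1 + 1 / n2))
    lfc <- m1 - m2
    t <- ifelse(se > 0, lfc / se, 0)
    dfTotal <- d0 + dg
    p <- 2 * pt(abs(t), df = dfTotal, lower.tail = FALSE)
    data.frame(gene_id = rownames(logcpm), log_fc = lfc,
               ave_expr = rowMeans(logcpm), t_mod = t,
               df_total = dfTotal, p_raw = pmin(1, p),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. A thin validated interface to
#' the standard step-up rule: adjusted values are monotone in the raw
#' ranks, elementwise at least the raw values, and capped at 1.
#'
#' @param p_raw vector of raw p-values in (0, 1].
#' @return vector of BH-adjusted p-values.
#' @export
adjustBH <- function(p_raw) {
    if (any(is.na(p_raw)) || any(p_raw <= 0) || any(p_raw > 1))
        stop("p-values must lie in (0, 1]")
    p.adjust(p_raw, method = "BH")
}

#' Flag differentially expressed genes
#'
#' Sets \code{is_de = (p_adj <= alpha)}; adds \code{p_adj} by
#' \code{\link{adjustBH}} if absent.
#'
#' @param table a DE table with column \code{p_raw} (and optionally
#'   \code{p_adj}).
#' @param alpha adjusted-P cutoff (default 0.1).
#' @return the table with \code{p_adj} and logical \code{is_de} columns;
#'   attribute \code{alpha} records the cutoff.
#' @export
callDE <- function(table, alpha = 0.1) {
    if (!("p_adj" %in% colnames(table)))
        table$p_adj <- adjustBH(table$p_raw)
    table$is_de <- table$p_adj <= alpha
    attr(table, "alpha") <- alpha
    table
}

#' Percent differentially expressed, at printed precision
#'
#' @param n_de number of DE genes.
#' @param n_expressed number of expressed genes.
#' @return \code{100 * n_de / n_expressed} rounded to one decimal.
#' @examples
#' percentDE(798, 8023)   # 9.9
#' percentDE(1568, 7687)  # 20.4
#' @export
percentDE <- function(n_de, n_expressed) round(100 * n_de / n_expressed, 1)

#' Latitudinal differential expression for one species and tissue
#'
#' The full per-contrast engine: TPM computation, expressed-gene filtering
#' on per-population median TPM, log2-CPM transformation (library sizes
#' from all genes), empirical-Bayes moderated t-test of low- vs
#' high-latitude samples, BH adjustment and DE calling.
#'
#' @param object a \linkS4class{CountsDataset}.
#' @param species,tissue the contrast cell to analyse.
#' @param populations named pair \code{c(low = ..., high = ...)}.
#' @param alpha adjusted-P cutoff for DE calls.
#' @param tpmThreshold strict median-TPM expression threshold.
#' @param priorCount prior count for the log2-CPM transform.
#' @return DE table (one row per expressed gene) with columns
#'   \code{gene_id}, \code{log_fc}, \code{ave_expr}, \code{t_mod},
#'   \code{df_total}, \code{p_raw}, \code{p_adj}, \code{is_de};
#'   attributes \code{species}, \code{tissue}, \code{n_expressed},
#'   \code{alpha}, \code{eb}, \code{median_tpm}.
#' @export
latitudinalDE <- function(object, species, tissue,
                          populations = c(low = "Panama", high = "Maine"),
                          alpha = 0.1, tpmThreshold = 1, priorCount = 0.5) {
    sub <- subsetSamples(object, species = species, tissue = tissue,
                         population = unname(populations))
    tpm <- computeTpm(sub)
    med <- medianPopulationTpm(tpm, sampleInfo(sub), species, tissue,
                               unname(populations))
    expressed <- filterExpressed(med, tpmThreshold)
    if (length(expressed) < 10L)
        stop("fewer than 10 expressed genes for ", species, "/", tissue)
    lc <- logCpm(sub, prior_count = priorCount)[expressed, , drop = FALSE]
    tab <- moderatedTTest(lc, sampleInfo(sub)$population,
                          contrast = c(populations[["low"]],
                                       populations[["high"]]))
    tab <- callDE(tab, alpha = alpha)
    attr(tab, "species") <- species
    attr(tab, "tissue") <- tissue
    attr(tab, "n_expressed") <- length(expressed)
    attr(tab, "median_tpm") <- med[expressed, , drop = FALSE]
    tab
}

#' Write / read a DE table
#'
#' TSV columns \code{gene_id, log_fc, ave_expr, t_mod, df_total, p_raw,
#' p_adj, is_de}, numerics at 6 significant digits.
#'
#' @param table a DE table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDETable <- function(table, path) {
    out <- table
    for (cn in c("log_fc", "ave_expr", "t_mod", "df_total", "p_raw",
                 "p_adj"))
        if (cn %in% colnames(out)) out[[cn]] <- fmt_num(out[[cn]])
    write_tsv(out, path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
    tab <- read_tsv_checked(path)
    if ("is_de" %in% colnames(tab)) tab$is_de <- as.logical(tab$is_de)
    tab
}
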