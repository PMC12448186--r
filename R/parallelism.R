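#' Join DE tables across species through an ortholog map
#'
#' Restricts the comparison to ortholog rows whose genes are expressed
#' (i.e. present in the DE table) in every species of the comparison, and
#' carries each species' log fold change, adjusted P and DE flag.
#'
#' @param tables named list of DE tables (names are species labels; each
#'   table holds only expressed genes, as returned by
#'   \code{\link{latitudinalDE}}).
#' @param map an \linkS4class{OrthologMap} covering those species.
#' @return data.frame with one row per jointly-expressed ortholog:
#'   \code{ortholog_row}, then per species \code{gene.<sp>},
#'   \code{log_fc.<sp>}, \code{p_adj.<sp>}, \code{is_de.<sp>}. Attribute
#'   \code{species} lists the species in map order.
#' @export
restrictToOrthologs <- function(tables, map) {
    sps <- orthologSpecies(map)
    absent <- setdiff(sps, names(tables))
    if (length(absent))
        stop("species missing from DE tables: ",
             paste(absent, collapse = ", "))
    tab <- orthologTable(map)
    keep <- rep(TRUE, nrow(tab))
    for (sp in sps)
        keep <- keep & (tab[[sp]] %in% tables[[sp]]$gene_id)
    tab <- tab[keep, , drop = FALSE]
    out <- data.frame(ortholog_row = which(keep))
    for (sp in sps) {
        de <- tables[[sp]]
        idx <- match(tab[[sp]], de$gene_id)
        out[[paste0("gene.", sp)]] <- tab[[sp]]
        out[[paste0("log_fc.", sp)]] <- de$log_fc[idx]
        out[[paste0("p_adj.", sp)]] <- de$p_adj[idx]
        out[[paste0("is_de.", sp)]] <- de$is_de[idx]
    }
    attr(out, "species") <- sps
    out
}

joined_species <- function(joined) {
    sps <- attr(joined, "species")
    if (is.null(sps))
        sps <- sub("^is_de\\.", "",
                   grep("^is_de\\.", colnames(joined), value = TRUE))
    sps
}

joined_matrix <- function(joined, prefix) {
    sps <- joined_species(joined)
    m <- as.matrix(joined[paste0(prefix, ".", sps)])
    colnames(m) <- sps
    m
}

#' Shared differential expression counts among orthologs
#'
#' @param joined output of \code{\link{restrictToOrthologs}}.
#' @return list with \code{k_obs} (orthologs DE in every species),
#'   \code{n_de_each} (per-species DE counts among orthologs) and
#'   \code{N} (jointly-expressed ortholog count).
#' @export
sharedDECounts <- function(joined) {
    if (nrow(joined) == 0L) stop("joined ortholog table is empty")
    de <- joined_matrix(joined, "is_de")
    list(k_obs = sum(rowSums(de) == ncol(de)),
         n_de_each = colSums(de),
         N = nrow(de))
}

#' Expected shared DE count under independence
#'
#' The independence product over the jointly-expressed ortholog universe:
#' pairwise \eqn{n_1 n_2 / N}, three-way \eqn{n_1 n_2 n_3 / N^2} (the
#' hypergeometric/permutation-null mean).
#'
#' @param n_de_each per-species DE counts among orthologs.
#' @param N jointly-expressed ortholog count.
#' @return expected shared count (real).
#' @export
expectedShared <- function(n_de_each, N) {
    if (N <= 0) stop("N must be positive")
    if (any(n_de_each > N)) stop("n_de cannot exceed N")
    prod(n_de_each) / N^(length(n_de_each) - 1)
}

#' Binomial test for excess shared DE
#'
#' One-sided upper-tail exact binomial: \eqn{P(X \ge k_{obs})} with
#' \eqn{X \sim Bin(N, \prod_i n_i/N)}.
#'
#' @inheritParams expectedShared
#' @param k_obs observed shared DE count.
#' @return p-value.
#' @export
sharedDEEnrichmentTest <- function(k_obs, n_de_each, N) {
    if (N <= 0 || k_obs < 0 || k_obs > N || any(n_de_each < 0) ||
        any(n_de_each > N))
        stop("invalid counts for the shared-DE enrichment test")
    p0 <- prod(n_de_each / N)
    pbinom(k_obs - 1, N, p0, lower.tail = FALSE)
}

#' Directionality concordance among orthologs
#'
#' An ortholog is concordant when its log fold changes have the same sign
#' in every species of the comparison. Orthologs with any exactly-zero
#' log fold change are ties and are excluded (with a warning) from both
#' numerator and denominator.
#'
#' @param joined output of \code{\link{restrictToOrthologs}}.
#' @param scope \code{"shared_de"} (restrict to orthologs DE in every
#'   species) or \code{"all"} (all jointly-expressed orthologs).
#' @return list with \code{k_same}, \code{n}, \code{pct} (=100 k/n) and
#'   \code{pct_higher_in_maine}: among concordant orthologs, the
#'   percentage whose common sign is negative, i.e. expression higher in
#'   the high-latitude population under the low-minus-high sign
#'   convention.
#' @export
signConcordance <- function(joined, scope = c("shared_de", "all")) {
    scope <- match.arg(scope)
    lfc <- joined_matrix(joined, "log_fc")
    if (scope == "shared_de") {
        de <- joined_matrix(joined, "is_de")
        lfc <- lfc[rowSums(de) == ncol(de), , drop = FALSE]
    }
    ties <- rowSums(lfc == 0) > 0
    if (any(ties)) {
        warning(sum(ties), " ortholog(s) with log_fc exactly 0 excluded ",
                "from directionality")
        lfc <- lfc[!ties, , drop = FALSE]
    }
    n <- nrow(lfc)
    if (n == 0L)
        return(list(k_same = 0L, n = 0L, pct = NA_real_,
                    pct_higher_in_maine = NA_real_))
    sgn <- sign(lfc)
    same <- rowSums(sgn == sgn[, 1]) == ncol(sgn)
    kSame <- sum(same)
    pctMaine <- if (kSame > 0) 100 * mean(sgn[same, 1] < 0) else NA_real_
    list(k_same = kSame, n = n, pct = 100 * kSame / n,
         pct_higher_in_maine = pctMaine)
}

#' Binomial test for excess directionality concordance
#'
#' One-sided upper-tail exact binomial \eqn{P(X \ge k_{same})},
#' \eqn{X \sim Bin(n, p_0)}, with \eqn{p_0} typically the concordant
#' fraction among all expressed orthologs.
#'
#' @param k_same concordant count.
#' @param n orthologs assessed.
#' @param p0 null concordance probability in (0, 1).
#' @return p-value.
#' @export
concordanceTest <- function(k_same, n, p0) {
    if (n < 0 || k_same < 0 || k_same > n) stop("invalid counts")
    if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
    pbinom(k_same - 1, n, p0, lower.tail = FALSE)
}

#' Spearman correlation of log fold changes between two species
#'
#' Rank correlation (average ranks for ties) of the latitudinal log fold
#' changes across jointly-expressed orthologs, with the t-approximation
#' p-value.
#'
#' @param joined output of \code{\link{restrictToOrthologs}} for a species
#'   pair.
#' @return list with \code{rho} and \code{p}.
#' @export
logfcCorrelation <- function(joined) {
    lfc <- joined_matrix(joined, "log_fc")
    if (ncol(lfc) != 2L)
        stop("log fold-change correlation is defined for a species pair; ",
             "run the pairwise comparisons separately")
    if (nrow(lfc) < 3L) stop("need at least 3 joined orthologs")
    if (var(lfc[, 1]) == 0 || var(lfc[, 2]) == 0)
        stop("undefined correlation: constant log fold-change vector")
    ct <- suppressWarnings(cor.test(lfc[, 1], lfc[, 2], method = "spearman",
                                    exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Full parallelism report for one species comparison in one tissue
#'
#' Assembles, for a species pair or triple: the jointly-expressed ortholog
#' universe, per-species and shared DE counts, the independence
#' expectation and its one-sided binomial enrichment test, directionality
#' concordance among shared DE orthologs (tested against the all-ortholog
#' concordant fraction), and (for pairs) the Spearman correlation of log
#' fold changes.
#'
#' @param tables named list of DE tables, one per species.
#' @param map \linkS4class{OrthologMap} for the comparison.
#' @param tissue tissue label carried through to the report.
#' @return a \code{ParallelismReport} list with fields \code{species},
#'   \code{tissue}, \code{N}, \code{n_de_each}, \code{k_obs},
#'   \code{expected_shared}, \code{enrichment_p},
#'   \code{pct_higher_in_maine}, \code{pct_same_direction_shared},
#'   \code{pct_same_direction_all}, \code{concordance_p},
#'   \code{spearman_rho}, \code{spearman_p}.
#' @export
parallelismReport <- function(tables, map, tissue = NA_character_) {
    joined <- restrictToOrthologs(tables, map)
    cnt <- sharedDECounts(joined)
    E <- expectedShared(cnt$n_de_each, cnt$N)
    enrP <- sharedDEEnrichmentTest(cnt$k_obs, cnt$n_de_each, cnt$N)
    allDir <- signConcordance(joined, "all")
    shDir <- signConcordance(joined, "shared_de")
    concP <- if (shDir$n > 0 && !is.na(allDir$pct) && allDir$pct > 0 &&
                 allDir$pct < 100)
        concordanceTest(shDir$k_same, shDir$n, allDir$pct / 100)
    else NA_real_
    rho <- p <- NA_real_
    if (length(joined_species(joined)) == 2L && nrow(joined) >= 3L) {
        ct <- logfcCorrelation(joined)
        rho <- ct$rho; p <- ct$p
    }
    structure(list(species = joined_species(joined), tissue = tissue,
                   N = cnt$N, n_de_each = cnt$n_de_each,
                   k_obs = cnt$k_obs, expected_shared = E,
                   enrichment_p = enrP,
                   pct_higher_in_maine = shDir$pct_higher_in_maine,
                   pct_same_direction_shared = shDir$pct,
                   pct_same_direction_all = allDir$pct,
                   concordance_p = concP,
                   spearman_rho = rho, spearman_p = p,
                   joined = joined),
              class = "ParallelismReport")
}

#' @export
print.ParallelismReport <- function(x, ...) {
    cat("Parallelism report:", paste(x$species, collapse = " vs "),
        if (!is.na(x$tissue)) paste0("(", x$tissue, ")"), "\n")
    cat(sprintf("  orthologs expressed in all: %d\n", x$N))
    cat(sprintf("  DE each: %s; shared %d (expected %.1f), binomial p = %.3g\n",
                paste(x$n_de_each, collapse = "/"), x$k_obs,
                x$expected_shared, x$enrichment_p))
    cat(sprintf("  same direction: %.0f%% of shared DE vs %.1f%% of all; p = %.3g\n",
                x$pct_same_direction_shared, x$pct_same_direction_all,
                x$concordance_p))
    if (!is.na(x$spearman_rho))
        cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho,
                    x$spearman_p))
    invisible(x)
}
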