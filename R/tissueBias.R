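#' Tissue-specificity index tau
#'
#' \eqn{\tau = \sum_i (1 - x_i/x_{max}) / (n - 1)} over tissues, computed
#' on log-transformed abundance (supply log2(TPM+1); values are clipped at
#' 0). 0 means uniform expression, 1 single-tissue expression. Genes with
#' zero maximal expression have undefined tau (\code{NA}).
#'
#' @param expr gene x tissue matrix of non-negative (log-scale)
#'   expression.
#' @return data.frame with \code{gene_id}, \code{tau},
#'   \code{argmax_tissue}.
#' @export
computeTau <- function(expr) {
    expr <- as.matrix(expr)
    if (ncol(expr) < 2L) stop("tau requires at least 2 tissues")
    if (is.null(rownames(expr)))
        rownames(expr) <- paste0("g", seq_len(nrow(expr)))
    if (is.null(colnames(expr)))
        colnames(expr) <- paste0("tissue", seq_len(ncol(expr)))
    expr[expr < 0] <- 0
    xmax <- apply(expr, 1, max)
    tau <- rowSums(1 - expr / ifelse(xmax == 0, 1, xmax)) / (ncol(expr) - 1)
    tau[xmax == 0] <- NA_real_
    arg <- colnames(expr)[max.col(expr, ties.method = "first")]
    arg[xmax == 0] <- NA_character_
    data.frame(gene_id = rownames(expr), tau = tau, argmax_tissue = arg,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Thresholds for the organ-vs-whole-male tissue-bias classifier
#'
#' The classifier works on two limma-style contrasts, both oriented as
#' (whole male - organ) on the log2 scale, so organ-enriched genes have a
#' strongly negative coefficient. Defaults are the calibrated values for
#' the accessory gland (AG) and testis: AG logFC cutoff -3.59, testis
#' -0.46; adjusted P <= 0.01; minimum organ TPM of 1 (AG) or 5 (testis);
#' average expression strictly > 0 for the AG, >= 0 for the testis; and a
#' (whole male - other organ) logFC of at least 1, depleting genes that
#' are instead enriched in the other organ.
#'
#' @param organ \code{"AG"} or \code{"testis"} (selects the defaults).
#' @param logfc_organ_vs_whole,p_adj_max,min_tpm,other_organ_logfc_min
#'   override any single threshold.
#' @param ave_expr_strict is the minimum average-expression bound strict
#'   (> 0) rather than non-strict (>= 0)?
#' @return a \code{BiasThresholds} list.
#' @export
biasThresholds <- function(organ = c("AG", "testis"),
                           logfc_organ_vs_whole = NULL,
                           p_adj_max = 0.01,
                           min_tpm = NULL,
                           ave_expr_strict = NULL,
                           other_organ_logfc_min = 1) {
    organ <- match.arg(organ)
    def <- switch(organ,
                  AG = list(logfc = -3.59, tpm = 1, strict = TRUE),
                  testis = list(logfc = -0.46, tpm = 5, strict = FALSE))
    th <- list(organ = organ,
               logfc_organ_vs_whole =
                   if (is.null(logfc_organ_vs_whole)) def$logfc
                   else logfc_organ_vs_whole,
               p_adj_max = p_adj_max,
               min_tpm = if (is.null(min_tpm)) def$tpm else min_tpm,
               ave_expr_strict =
                   if (is.null(ave_expr_strict)) def$strict
                   else ave_expr_strict,
               other_organ_logfc_min = other_organ_logfc_min)
    if (th$p_adj_max <= 0 || th$p_adj_max >= 1)
        stop("p_adj_max must be in (0, 1)")
    if (th$min_tpm < 0) stop("min_tpm must be >= 0")
    class(th) <- "BiasThresholds"
    th
}

#' Classify organ-biased genes from organ-vs-whole-male contrasts
#'
#' A gene is organ-biased iff all of: (whole male - organ) logFC at or
#' below the organ cutoff; adjusted P at or below the maximum; organ
#' median TPM at least the minimum; average expression above (or at, per
#' the strictness flag) zero; and (whole male - other organ) logFC at
#' least the other-organ minimum.
#'
#' @param organVsWhole DE table of the (whole male - organ) contrast.
#' @param otherVsWhole DE table of the (whole male - other organ)
#'   contrast, on the same gene universe.
#' @param organTpm named per-gene median TPM in the organ.
#' @param thresholds a \code{\link{biasThresholds}} object.
#' @return character vector of organ-biased gene ids.
#' @export
classifyTissueBias <- function(organVsWhole, otherVsWhole, organTpm,
                               thresholds) {
    if (!setequal(organVsWhole$gene_id, otherVsWhole$gene_id))
        stop("the two contrast tables must share the same gene universe")
    idx <- match(organVsWhole$gene_id, otherVsWhole$gene_id)
    tpm <- organTpm[organVsWhole$gene_id]
    if (anyNA(tpm)) stop("organTpm must cover the contrast gene universe")
    ave_ok <- if (thresholds$ave_expr_strict) organVsWhole$ave_expr > 0
              else organVsWhole$ave_expr >= 0
    ok <- organVsWhole$log_fc <= thresholds$logfc_organ_vs_whole &
        organVsWhole$p_adj <= thresholds$p_adj_max &
        tpm >= thresholds$min_tpm &
        ave_ok &
        otherVsWhole$log_fc[idx] >= thresholds$other_organ_logfc_min
    organVsWhole$gene_id[ok]
}

#' Calibrate tissue-bias thresholds against tau-based calls
#'
#' Grid search over candidate thresholds maximising the Jaccard overlap
#' between the tau-based tissue-biased set (tau >= cutoff on a multi-tissue
#' reference, highest in the target organ) and the threshold-based set;
#' ties are broken towards stricter thresholds (more negative organ logFC,
#' then higher minimum TPM, lower adjusted-P bound, higher other-organ
#' bound).
#'
#' @param tauBiased character vector of tau-based biased gene ids
#'   (non-empty).
#' @param organVsWhole,otherVsWhole,organTpm as in
#'   \code{\link{classifyTissueBias}}.
#' @param grid named list of candidate values for any of
#'   \code{logfc_organ_vs_whole}, \code{p_adj_max}, \code{min_tpm},
#'   \code{other_organ_logfc_min}; fields not supplied stay at the organ
#'   default.
#' @param organ \code{"AG"} or \code{"testis"}.
#' @return the selected \code{BiasThresholds}, with attributes
#'   \code{jaccard} and \code{n_selected}.
#' @export
calibrateThresholds <- function(tauBiased, organVsWhole, otherVsWhole,
                                organTpm, grid, organ = "AG") {
    if (length(tauBiased) == 0L)
        stop("the tau-based gene set is empty; cannot calibrate")
    base <- biasThresholds(organ)
    fields <- c("logfc_organ_vs_whole", "p_adj_max", "min_tpm",
                "other_organ_logfc_min")
    for (f in setdiff(fields, names(grid))) grid[[f]] <- base[[f]]
    cells <- expand.grid(grid[fields], KEEP.OUT.ATTRS = FALSE)
    ## strictness order for tie-breaks
    ord <- order(cells$logfc_organ_vs_whole, -cells$min_tpm,
                 cells$p_adj_max, -cells$other_organ_logfc_min)
    cells <- cells[ord, , drop = FALSE]
    best <- NULL; bestJ <- -1
    for (r in seq_len(nrow(cells))) {
        th <- biasThresholds(organ,
                             logfc_organ_vs_whole =
                                 cells$logfc_organ_vs_whole[r],
                             p_adj_max = cells$p_adj_max[r],
                             min_tpm = cells$min_tpm[r],
                             other_organ_logfc_min =
                                 cells$other_organ_logfc_min[r])
        sel <- classifyTissueBias(organVsWhole, otherVsWhole, organTpm, th)
        j <- length(intersect(sel, tauBiased)) /
            length(union(sel, tauBiased))
        if (j > bestJ) {
            bestJ <- j; best <- th
            attr(best, "jaccard") <- j
            attr(best, "n_selected") <- length(sel)
        }
    }
    best
}
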