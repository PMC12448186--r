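#' 2x2 contingency table for class x condition
#'
#' Cell layout: \code{a} = class & condition, \code{b} = not-class &
#' condition, \code{c} = class & not-condition, \code{d} = not-class &
#' not-condition.
#'
#' @param a,b,c,d non-negative integer cell counts, total > 0.
#' @param condition,class labels for the two dichotomies.
#' @return a \code{ContingencyTable2x2} object.
#' @export
contingencyTable2x2 <- function(a, b, c, d, condition = "condition",
                                class = "class") {
    cells <- c(a = a, b = b, c = c, d = d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if (sum(cells) == 0) stop("table total must be positive")
    structure(list(a = a, b = b, c = c, d = d, condition = condition,
                   class = class, total = a + b + c + d),
              class = "ContingencyTable2x2")
}

#' @export
print.ContingencyTable2x2 <- function(x, ...) {
    m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
                dimnames = list(c(x$condition, paste("not", x$condition)),
                                c(x$class, paste("not", x$class))))
    print(m)
    invisible(x)
}

#' Cross-tabulate class membership against DE status
#'
#' Over the expressed universe of a DE table: \code{a} = class & DE,
#' \code{b} = not-class & DE, \code{c} = class & not-DE, \code{d} =
#' not-class & not-DE; total equals the expressed-gene count.
#'
#' @param de DE table with \code{gene_id} and logical \code{is_de}.
#' @param geneSet a \linkS4class{GeneSet}.
#' @return a \code{ContingencyTable2x2}.
#' @export
buildDETable <- function(de, geneSet) {
    inClass <- de$gene_id %in% members(geneSet)
    if (!any(inClass))
        stop("gene set '", geneSetLabel(geneSet),
             "' does not intersect the expressed universe")
    contingencyTable2x2(sum(inClass & de$is_de),
                        sum(!inClass & de$is_de),
                        sum(inClass & !de$is_de),
                        sum(!inClass & !de$is_de),
                        condition = "DE", class = geneSetLabel(geneSet))
}

#' Cross-tabulate class membership against log fold-change sign
#'
#' \code{a} = class & positive logFC, \code{b} = not-class & positive,
#' \code{c} = class & negative, \code{d} = not-class & negative, over all
#' expressed genes. Genes with logFC exactly 0 are counted in neither
#' sign class (warning) and reduce the table total.
#'
#' @param de DE table with \code{gene_id} and \code{log_fc}.
#' @param geneSet a \linkS4class{GeneSet}.
#' @return a \code{ContingencyTable2x2}.
#' @export
buildDirectionTable <- function(de, geneSet) {
    zero <- de$log_fc == 0
    if (any(zero)) {
        warning(sum(zero), " gene(s) with log_fc exactly 0 excluded from ",
                "the direction table")
        de <- de[!zero, , drop = FALSE]
    }
    inClass <- de$gene_id %in% members(geneSet)
    if (!any(inClass))
        stop("gene set '", geneSetLabel(geneSet),
             "' does not intersect the expressed universe")
    pos <- de$log_fc > 0
    contingencyTable2x2(sum(inClass & pos), sum(!inClass & pos),
                        sum(inClass & !pos), sum(!inClass & !pos),
                        condition = "+logFC", class = geneSetLabel(geneSet))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value by summation of all hypergeometric
#' probabilities not exceeding that of the observed table, with the
#' conditional maximum-likelihood odds ratio. A zero margin gives p = 1
#' and an undefined odds ratio (with a warning).
#'
#' @param table a \code{ContingencyTable2x2}.
#' @return list with \code{odds_ratio} and \code{p}.
#' @export
fisherExact <- function(table) {
    with(table, {
        if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
            warning("zero margin: p = 1, odds ratio undefined")
            return(list(odds_ratio = NA_real_, p = 1))
        }
        ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
        list(odds_ratio = unname(ft$estimate), p = ft$p.value)
    })
}

#' Enrichment percentages and fold
#'
#' \code{pct_in} = 100 a/(a+b) (class share inside the condition),
#' \code{pct_out} = 100 c/(c+d) (class share outside it) and their fold
#' ratio. Zero margins yield \code{NA} with a warning.
#'
#' @param table a \code{ContingencyTable2x2}.
#' @return list with \code{pct_in}, \code{pct_out}, \code{fold}.
#' @export
enrichmentSummary <- function(table) {
    with(table, {
        if ((a + b) == 0 || (c + d) == 0) {
            warning("zero condition margin: percentages undefined")
            return(list(pct_in = NA_real_, pct_out = NA_real_,
                        fold = NA_real_))
        }
        pin <- 100 * a / (a + b)
        pout <- 100 * c / (c + d)
        list(pct_in = pin, pct_out = pout,
             fold = if (pout == 0) NA_real_ else pin / pout)
    })
}
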