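#' Per-gene quartet expression profiles
#'
#' Builds, for one species and tissue, the four-population expression
#' profile used by the branch-length decomposition: log2(median TPM +
#' pseudo-count) for the two focal populations and the two outgroup
#' populations that root the quartet.
#'
#' @param tpm gene x sample TPM matrix.
#' @param info sample metadata (\code{\link{sampleInfo}}).
#' @param species,tissue cell to analyse.
#' @param focal length-2 character vector of focal population labels
#'   (order is preserved in the output).
#' @param outgroups length-2 character vector of outgroup labels.
#' @param pseudo pseudo-count added before the log (default 1).
#' @param genes optional gene ids to restrict to (e.g. the expressed set).
#' @return gene x 4 matrix of log2-scale profiles, columns named by
#'   population.
#' @export
quartetProfiles <- function(tpm, info, species, tissue,
                            focal = c("Maine", "Panama"),
                            outgroups = c("Madagascar", "Zimbabwe"),
                            pseudo = 1, genes = NULL) {
    if (pseudo <= 0) stop("pseudo-count must be > 0")
    pops <- c(focal, outgroups)
    if (length(pops) != 4L) stop("need two focal and two outgroup labels")
    med <- medianPopulationTpm(tpm, info, species, tissue, pops)
    if (!is.null(genes)) med <- med[genes, , drop = FALSE]
    log2(med + pseudo)
}

#' Pairwise per-gene expression distances of a quartet
#'
#' Absolute differences of the log2-scale profiles for all six unordered
#' population pairs.
#'
#' @param profile gene x 4 matrix (columns: focal1, focal2, outgroup1,
#'   outgroup2), as from \code{\link{quartetProfiles}}.
#' @return gene x 6 matrix with columns \code{f1.f2}, \code{f1.o1},
#'   \code{f1.o2}, \code{f2.o1}, \code{f2.o2}, \code{o1.o2}.
#' @export
quartetDistances <- function(profile) {
    profile <- as.matrix(profile)
    if (ncol(profile) != 4L) stop("profile must have 4 population columns")
    d <- cbind(f1.f2 = abs(profile[, 1] - profile[, 2]),
               f1.o1 = abs(profile[, 1] - profile[, 3]),
               f1.o2 = abs(profile[, 1] - profile[, 4]),
               f2.o1 = abs(profile[, 2] - profile[, 3]),
               f2.o2 = abs(profile[, 2] - profile[, 4]),
               o1.o2 = abs(profile[, 3] - profile[, 4]))
    rownames(d) <- rownames(profile)
    d
}

#' Terminal branch lengths to the two focal populations
#'
#' Three-point (Steiner) estimates on the fixed topology
#' ((outgroup1, outgroup2), (focal1, focal2)): for each outgroup o,
#' \eqn{b_1 = (d(f_1,o) + d(f_1,f_2) - d(f_2,o))/2}, floored at 0, then
#' averaged over the two outgroups; symmetrically for \eqn{b_2}. Branch
#' lengths are invariant to adding a constant to all four profile values
#' and swap when the focal populations swap.
#'
#' @param distances gene x 6 distance matrix from
#'   \code{\link{quartetDistances}}.
#' @return data.frame with \code{gene_id}, \code{b_focal1},
#'   \code{b_focal2}.
#' @export
terminalBranches <- function(distances) {
    d <- as.matrix(distances)
    need <- c("f1.f2", "f1.o1", "f1.o2", "f2.o1", "f2.o2")
    if (!all(need %in% colnames(d)))
        stop("distances must carry the quartetDistances columns")
    floor0 <- function(x) pmax(x, 0)
    b1 <- (floor0((d[, "f1.o1"] + d[, "f1.f2"] - d[, "f2.o1"]) / 2) +
           floor0((d[, "f1.o2"] + d[, "f1.f2"] - d[, "f2.o2"]) / 2)) / 2
    b2 <- (floor0((d[, "f2.o1"] + d[, "f1.f2"] - d[, "f1.o1"]) / 2) +
           floor0((d[, "f2.o2"] + d[, "f1.f2"] - d[, "f1.o2"]) / 2)) / 2
    data.frame(gene_id = rownames(d), b_focal1 = b1, b_focal2 = b2,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene lineage-specific expression divergence table
#'
#' Convenience wrapper: quartet profiles, distances and terminal branch
#' lengths in one call.
#'
#' @inheritParams quartetProfiles
#' @return data.frame with \code{gene_id} and one branch-length column per
#'   focal population (named \code{b_<population>}); attribute
#'   \code{focal} records the population labels.
#' @export
ledTable <- function(tpm, info, species, tissue,
                     focal = c("Maine", "Panama"),
                     outgroups = c("Madagascar", "Zimbabwe"),
                     pseudo = 1, genes = NULL) {
    prof <- quartetProfiles(tpm, info, species, tissue, focal, outgroups,
                            pseudo, genes)
    br <- terminalBranches(quartetDistances(prof))
    colnames(br) <- c("gene_id", paste0("b_", focal))
    attr(br, "focal") <- focal
    br
}

#' Mean branch lengths per gene set and population
#'
#' @param led output of \code{\link{ledTable}}.
#' @param sets named list of gene-id vectors (\code{NULL} entry = all
#'   genes).
#' @return data.frame with \code{set}, \code{population},
#'   \code{mean_led}, \code{n}.
#' @export
ledSummary <- function(led, sets = list(All = NULL)) {
    focal <- attr(led, "focal")
    if (is.null(focal)) focal <- sub("^b_", "", colnames(led)[-1])
    rows <- list()
    for (nm in names(sets)) {
        ids <- sets[[nm]]
        sub <- if (is.null(ids)) led else led[led$gene_id %in% ids, ,
                                              drop = FALSE]
        for (p in focal)
            rows[[paste(nm, p)]] <- data.frame(
                set = nm, population = p,
                mean_led = mean(sub[[paste0("b_", p)]]),
                n = nrow(sub))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Welch t-test between branch-length vectors
#'
#' Either between the two focal populations over one gene set
#' (\code{ids2 = NULL}), or between two gene sets within one population.
#' Both compared vectors need at least 2 genes; a zero-variance pair is
#' flagged with \code{p = NA}.
#'
#' @param led output of \code{\link{ledTable}}.
#' @param ids1 gene ids of the (first) set; \code{NULL} = all genes.
#' @param ids2 gene ids of the second set, for a between-set comparison.
#' @param population population for a between-set comparison; ignored for
#'   the between-population comparison.
#' @return list with \code{mean1}, \code{mean2}, \code{p}.
#' @export
ledTest <- function(led, ids1 = NULL, ids2 = NULL, population = NULL) {
    focal <- attr(led, "focal")
    if (is.null(focal)) focal <- sub("^b_", "", colnames(led)[-1])
    pick <- function(ids) if (is.null(ids)) led
                          else led[led$gene_id %in% ids, , drop = FALSE]
    if (is.null(ids2)) {
        sub <- pick(ids1)
        x <- sub[[paste0("b_", focal[1])]]
        y <- sub[[paste0("b_", focal[2])]]
    } else {
        if (is.null(population)) population <- focal[1]
        x <- pick(ids1)[[paste0("b_", population)]]
        y <- pick(ids2)[[paste0("b_", population)]]
    }
    if (length(x) < 2L || length(y) < 2L)
        stop("each compared set needs at least 2 genes")
    p <- tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
    list(mean1 = mean(x), mean2 = mean(y), p = p)
}
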