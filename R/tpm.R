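#' Transcripts per million from read counts and gene lengths
#'
#' \eqn{TPM_{gs} = 10^6 \, (c_{gs}/\ell_g) / \sum_{g'} (c_{g's}/\ell_{g'})}
#' with \eqn{\ell} the transcript length in kilobases. Each sample column
#' sums to 1e6; an all-zero sample yields an all-zero column.
#'
#' @param object a \linkS4class{CountsDataset}.
#' @return gene x sample numeric matrix of TPM values.
#' @export
computeTpm <- function(object) {
    m <- counts(object)
    rate <- m / (geneLengths(object) / 1000)
    tot <- colSums(rate)
    tpm <- sweep(rate, 2, ifelse(tot == 0, 1, tot), "/") * 1e6
    tpm[, tot == 0] <- 0
    tpm
}

#' Per-population median TPM
#'
#' Median TPM across the replicate columns of each requested population,
#' for one species and tissue.
#'
#' @param tpm gene x sample TPM matrix (from \code{\link{computeTpm}}).
#' @param info sample metadata data.frame (\code{\link{sampleInfo}}).
#' @param species,tissue the species and tissue to restrict to.
#' @param populations population labels; default all present.
#' @return gene x population matrix of median TPM.
#' @export
medianPopulationTpm <- function(tpm, info, species, tissue,
                                populations = NULL) {
    info <- info[info$species == species & info$tissue == tissue, ,
                 drop = FALSE]
    if (is.null(populations)) populations <- unique(info$population)
    absent <- setdiff(populations, info$population)
    if (length(absent))
        stop("population absent for ", species, "/", tissue, ": ",
             paste(absent, collapse = ", "))
    med <- vapply(populations, function(p) {
        cols <- as.character(info$sample_id[info$population == p])
        apply(tpm[, cols, drop = FALSE], 1, median)
    }, numeric(nrow(tpm)))
    med <- matrix(med, nrow = nrow(tpm),
                  dimnames = list(rownames(tpm), populations))
    med
}

#' Expressed-gene filter
#'
#' A gene is "expressed" when its median TPM strictly exceeds the
#' threshold in at least one of the two focal populations.
#'
#' @param medians gene x population matrix of median TPM with exactly two
#'   (focal) columns.
#' @param threshold strict lower bound on median TPM (default 1).
#' @return character vector of expressed gene ids, in input order.
#' @export
filterExpressed <- function(medians, threshold = 1) {
    if (ncol(medians) != 2L)
        stop("filterExpressed expects exactly two focal populations")
    rownames(medians)[apply(medians > threshold, 1, any)]
}
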