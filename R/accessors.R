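#' Accessors for the core classes
#'
#' \code{counts} returns the read-count matrix; \code{geneIds} and
#' \code{geneLengths} the gene identifiers and transcript lengths;
#' \code{sampleInfo} the sample metadata as a base data.frame;
#' \code{orthologSpecies} and \code{orthologTable} the species labels and the
#' gene-id table of an \linkS4class{OrthologMap}; \code{members} and
#' \code{geneSetLabel} the contents of a \linkS4class{GeneSet}.
#'
#' @param object a \linkS4class{CountsDataset}, \linkS4class{OrthologMap}
#'   or \linkS4class{GeneSet}.
#' @param ... ignored.
#' @return the requested component.
#' @name accessors
#' @aliases counts counts,CountsDataset-method geneIds geneLengths sampleInfo
#'   orthologSpecies orthologTable members geneSetLabel geneSetSpecies
NULL

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "CountsDataset", function(object, ...) {
    assay(object, "counts")
})

#' @rdname accessors
#' @export
geneIds <- function(object) rownames(object)

#' @rdname accessors
#' @export
geneLengths <- function(object) {
    setNames(rowData(object)$length, rownames(object))
}

#' @rdname accessors
#' @export
sampleInfo <- function(object) {
    as.data.frame(colData(object))
}

#' @rdname accessors
#' @export
orthologSpecies <- function(object) object@speciesIds

#' @rdname accessors
#' @export
orthologTable <- function(object) object@table

#' @rdname accessors
#' @export
members <- function(object) object@members

#' @rdname accessors
#' @export
geneSetLabel <- function(object) object@label

#' @rdname accessors
#' @export
geneSetSpecies <- function(object) object@species

#' Subset a CountsDataset by sample metadata
#'
#' Convenience filter returning the samples matching any combination of
#' species, population and tissue.
#'
#' @param object a \linkS4class{CountsDataset}.
#' @param species,population,tissue optional character vectors; \code{NULL}
#'   keeps all.
#' @return a \linkS4class{CountsDataset} with the selected samples.
#' @export
subsetSamples <- function(object, species = NULL, population = NULL,
                          tissue = NULL) {
    cd <- colData(object)
    keep <- rep(TRUE, ncol(object))
    if (!is.null(species))    keep <- keep & cd$species %in% species
    if (!is.null(population)) keep <- keep & cd$population %in% population
    if (!is.null(tissue))     keep <- keep & cd$tissue %in% tissue
    if (!any(keep))
        stop("no samples match the requested species/population/tissue")
    object[, keep]
}
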