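#' @import methods
#' @importFrom stats median pbinom dbinom pt qnorm rnorm runif rnbinom rpois
#'   p.adjust var cor cor.test t.test fisher.test setNames complete.cases
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

REQUIRED_SAMPLE_FIELDS <- c("sample_id", "species", "population", "tissue",
                            "replicate")

#' CountsDataset: read counts with gene lengths and sample metadata
#'
#' The raw input of the pipeline: a gene x sample matrix of non-negative
#' integer read counts (as produced by a counting tool such as featureCounts),
#' per-gene transcript lengths in base pairs, and per-sample metadata
#' identifying species, population, tissue and replicate. Implemented as a
#' \linkS4class{SummarizedExperiment} with a single \code{"counts"} assay,
#' a \code{length} column in \code{rowData}, and the sample fields in
#' \code{colData}.
#'
#' Validity requires: dimensions consistent; counts integral and
#' non-negative; lengths strictly positive; gene ids and sample ids unique;
#' the (species, population, tissue, replicate) combination unique across
#' samples.
#'
#' @aliases CountsDataset-class
#' @exportClass CountsDataset
setClass("CountsDataset", contains = "SummarizedExperiment")

setValidity("CountsDataset", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (any(is.na(m)))
            msg <- c(msg, "counts must not contain missing values")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m))) msg <- c(msg, "counts must be integers")
        }
    }
    gn <- rownames(object)
    if (is.null(gn) || anyNA(gn) || any(gn == ""))
        msg <- c(msg, "gene ids (rownames) are required")
    else if (anyDuplicated(gn))
        msg <- c(msg, sprintf("duplicate gene id: %s",
                              paste(unique(gn[duplicated(gn)]), collapse = ", ")))
    if (!("length" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData column 'length' is required")
    else if (any(is.na(rowData(object)$length)) ||
             any(rowData(object)$length <= 0))
        msg <- c(msg, "all gene lengths must be > 0")
    cd <- colData(object)
    miss <- setdiff(REQUIRED_SAMPLE_FIELDS, colnames(cd))
    if (length(miss))
        msg <- c(msg, sprintf("colData is missing field(s): %s",
                              paste(miss, collapse = ", ")))
    else {
        sid <- as.character(cd$sample_id)
        if (anyDuplicated(sid))
            msg <- c(msg, sprintf("duplicate sample id: %s",
                                  paste(unique(sid[duplicated(sid)]),
                                        collapse = ", ")))
        key <- paste(cd$species, cd$population, cd$tissue, cd$replicate,
                     sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg,
                     "(species, population, tissue, replicate) must be unique")
        if (any(is.na(cd$replicate)) || any(cd$replicate < 1) ||
            any(cd$replicate != round(cd$replicate)))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CountsDataset
#'
#' @param counts gene x sample matrix of non-negative integer read counts,
#'   with gene ids as rownames and sample ids as colnames.
#' @param lengths numeric vector of per-gene transcript lengths in base
#'   pairs, in the row order of \code{counts} (or named by gene id).
#' @param sampleInfo data.frame with one row per sample and columns
#'   \code{sample_id}, \code{species}, \code{population}, \code{tissue},
#'   \code{replicate}, covering every column of \code{counts}.
#' @return a validated \linkS4class{CountsDataset}.
#' @examples
#' cds <- CountsDataset(
#'   counts = matrix(c(10L, 0L, 5L, 5L), 2, byrow = TRUE,
#'                   dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   lengths = c(1000, 2000),
#'   sampleInfo = data.frame(sample_id = c("s1", "s2"), species = "Dmel",
#'                           population = c("Maine", "Panama"),
#'                           tissue = "AG", replicate = 1L))
#' counts(cds)
#' @export
CountsDataset <- function(counts, lengths, sampleInfo) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (!is.null(names(lengths)) && !is.null(rownames(counts)))
        lengths <- lengths[rownames(counts)]
    sampleInfo <- as.data.frame(sampleInfo)
    miss <- setdiff(REQUIRED_SAMPLE_FIELDS, colnames(sampleInfo))
    if (length(miss))
        stop("sampleInfo is missing field(s): ", paste(miss, collapse = ", "))
    if (!is.null(colnames(counts))) {
        absent <- setdiff(colnames(counts),
                          as.character(sampleInfo$sample_id))
        if (length(absent))
            stop("sample missing from metadata: ",
                 paste(absent, collapse = ", "))
        sampleInfo <- sampleInfo[match(colnames(counts),
                                       as.character(sampleInfo$sample_id)), ,
                                 drop = FALSE]
    }
    rownames(sampleInfo) <- as.character(sampleInfo$sample_id)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(length = as.numeric(lengths),
                            row.names = rownames(counts)),
        colData = DataFrame(sampleInfo))
    new("CountsDataset", se)
}

#' OrthologMap: 1:1 (or 1:1:1) gene correspondences between species
#'
#' Each row maps one gene per species; a gene id may appear in at most one
#' row of its species' column, enforcing the one-to-one property.
#'
#' @slot speciesIds character vector of 2 or 3 species labels.
#' @slot table data.frame of gene ids, one column per species.
#' @aliases OrthologMap-class
#' @exportClass OrthologMap
setClass("OrthologMap",
         representation(speciesIds = "character", table = "data.frame"))

setValidity("OrthologMap", function(object) {
    msg <- character()
    k <- length(object@speciesIds)
    if (k < 2L || k > 3L)
        msg <- c(msg, "speciesIds must name 2 or 3 species")
    if (anyDuplicated(object@speciesIds))
        msg <- c(msg, "speciesIds must be distinct")
    if (ncol(object@table) != k)
        msg <- c(msg, "table must have one column per species")
    tab <- object@table
    if (any(vapply(tab, function(x) anyNA(x) || any(x == ""), logical(1))))
        msg <- c(msg, "null or empty gene ids are not permitted")
    for (s in seq_len(ncol(tab))) {
        g <- as.character(tab[[s]])
        if (anyDuplicated(g))
            msg <- c(msg, sprintf("gene %s not 1:1",
                                  paste(unique(g[duplicated(g)]),
                                        collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OrthologMap
#'
#' @param table data.frame of gene ids with one column per species; column
#'   names are taken as the species labels unless \code{speciesIds} is given.
#' @param speciesIds optional character vector of species labels.
#' @return a validated \linkS4class{OrthologMap}.
#' @export
OrthologMap <- function(table, speciesIds = colnames(table)) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    table[] <- lapply(table, as.character)
    colnames(table) <- speciesIds
    new("OrthologMap", speciesIds = as.character(speciesIds), table = table)
}

#' GeneSet: a labelled set of gene ids for one species
#'
#' Used for gene classes such as seminal fluid proteins (Sfp), transcription
#' factors, or single-cell marker sets. Members are de-duplicated at
#' construction.
#'
#' @slot label class label, e.g. "Sfp".
#' @slot species species the gene ids belong to.
#' @slot members character vector of gene ids (unique, non-empty).
#' @aliases GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet",
         representation(label = "character", species = "character",
                        members = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@members) == 0L)
        msg <- c(msg, "members must be non-empty")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (anyNA(object@members) || any(object@members == ""))
        msg <- c(msg, "empty gene ids are not permitted")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param members character vector of gene ids; duplicates are dropped.
#' @param label class label.
#' @param species species label (free string).
#' @return a validated \linkS4class{GeneSet}.
#' @export
GeneSet <- function(members, label, species = NA_character_) {
    new("GeneSet", label = as.character(label),
        species = as.character(species),
        members = unique(as.character(members)))
}

setMethod("show", "CountsDataset", function(object) {
    cat("CountsDataset with", nrow(object), "genes and", ncol(object),
        "samples\n")
    cd <- colData(object)
    cat("  species:    ", paste(unique(cd$species), collapse = ", "), "\n")
    cat("  populations:", paste(unique(cd$population), collapse = ", "), "\n")
    cat("  tissues:    ", paste(unique(cd$tissue), collapse = ", "), "\n")
})

setMethod("show", "OrthologMap", function(object) {
    cat("OrthologMap:", nrow(object@table), "rows across",
        paste(object@speciesIds, collapse = " / "), "\n")
})

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@label, "' (", object@species, "): ",
        length(object@members), " genes\n", sep = "")
})
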