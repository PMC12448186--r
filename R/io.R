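## Tab-separated readers/writers for every file the pipeline touches.
## Dialect: UTF-8, header row required, gene ids opaque strings, no missing
## values in counts (0 is the only representation of "not detected").

read_tsv_checked <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

## Numeric formatting used by all writers: 6 significant digits, so that
## write(read(x)) round-trips byte-identically modulo float formatting.
fmt_num <- function(x) signif(x, 6)

#' Read a counts dataset from TSV files
#'
#' Reads a gene x sample count matrix (first column \code{gene_id}, one
#' column per sample), a gene-length table (\code{gene_id},
#' \code{length_bp}) and a sample-metadata table (\code{sample_id},
#' \code{species}, \code{population}, \code{tissue}, \code{replicate}),
#' and returns a validated \linkS4class{CountsDataset}. Gene and sample
#' order is preserved from the files.
#'
#' @param countsPath,metadataPath,lengthsPath paths to the three TSV files.
#' @return a \linkS4class{CountsDataset}.
#' @seealso [writeCounts()] for the inverse operation.
#' @export
readCounts <- function(countsPath, metadataPath, lengthsPath) {
    ctab <- read_tsv_checked(countsPath)
    if (colnames(ctab)[1] != "gene_id")
        stop("counts file must have a leading 'gene_id' column: ", countsPath)
    genes <- as.character(ctab$gene_id)
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicate gene id: ", paste(dup, collapse = ", "))
    m <- as.matrix(ctab[, -1, drop = FALSE])
    bad <- which(is.na(m) | m != round(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                     genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
    rownames(m) <- genes

    ltab <- read_tsv_checked(lengthsPath)
    if (!all(c("gene_id", "length_bp") %in% colnames(ltab)))
        stop("lengths file must have columns gene_id, length_bp: ",
             lengthsPath)
    if (!setequal(ltab$gene_id, genes))
        stop("lengths file does not cover the count matrix gene ids")
    lengths <- setNames(as.numeric(ltab$length_bp),
                        as.character(ltab$gene_id))[genes]

    meta <- read_tsv_checked(metadataPath)
    absent <- setdiff(colnames(m), as.character(meta$sample_id))
    if (length(absent))
        stop("sample missing from metadata: ", paste(absent, collapse = ", "))
    CountsDataset(m, lengths, meta)
}

#' Write a counts dataset to TSV files
#'
#' @param object a \linkS4class{CountsDataset}.
#' @param countsPath,metadataPath,lengthsPath output paths.
#' @return invisibly, the three paths.
#' @export
writeCounts <- function(object, countsPath, metadataPath, lengthsPath) {
    m <- counts(object)
    write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              countsPath)
    write_tsv(data.frame(gene_id = rownames(m),
                         length_bp = fmt_num(geneLengths(object)),
                         check.names = FALSE),
              lengthsPath)
    write_tsv(sampleInfo(object)[REQUIRED_SAMPLE_FIELDS], metadataPath)
    invisible(c(countsPath, metadataPath, lengthsPath))
}

#' Read an ortholog map from TSV
#'
#' One gene-id column per species; rows are 1:1 (or 1:1:1) correspondences.
#' Any gene appearing in more than one row makes the whole file invalid.
#'
#' @param path path to the TSV file.
#' @param nSpecies expected number of species columns (2 or 3).
#' @return an \linkS4class{OrthologMap}.
#' @export
readOrthologMap <- function(path, nSpecies) {
    tab <- read_tsv_checked(path)
    if (ncol(tab) != nSpecies)
        stop(sprintf("expected %d species columns, found %d in %s",
                     nSpecies, ncol(tab), path))
    OrthologMap(tab)
}

#' @rdname readOrthologMap
#' @param object an \linkS4class{OrthologMap} to write.
#' @export
writeOrthologMap <- function(object, path) {
    write_tsv(orthologTable(object), path)
    invisible(path)
}

#' Read a gene set from TSV
#'
#' One gene id per line under a \code{gene_id} header (a single unnamed
#' column is also accepted). Membership is de-duplicated; an empty file is
#' an error.
#'
#' @param path path to the file.
#' @param label class label to attach (e.g. "Sfp").
#' @param species species label.
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, label, species = NA_character_) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty gene set file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (identical(ids[1], "gene_id")) ids <- ids[-1]
    if (length(ids) == 0L) stop("empty gene set file: ", path)
    GeneSet(ids, label = label, species = species)
}

#' @rdname readGeneSet
#' @param object a \linkS4class{GeneSet} to write.
#' @export
writeGeneSet <- function(object, path) {
    write_tsv(data.frame(gene_id = members(object),
                         label = geneSetLabel(object)), path)
    invisible(path)
}
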