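#' Read a genome collection from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that enforces the
#' collection invariants downstream code relies on: unique non-empty record
#' ids, non-empty sequences, and an A/C/G/T/N alphabet (sequences are
#' uppercased). Gzip-compressed files are read transparently.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "acgt"), fa)
#' readGenomes(fa)
#' @export
readGenomes <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    x <- Biostrings::readDNAStringSet(path)
    # keep only the first whitespace-delimited token of each header
    names(x) <- sub("\\s.*$", "", names(x))
    if (any(names(x) == ""))
        stop("FASTA record with empty id in ", path)
    dup <- unique(names(x)[duplicated(names(x))])
    if (length(dup))
        stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
    if (any(Biostrings::width(x) == 0L)) {
        bad <- names(x)[Biostrings::width(x) == 0L]
        stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
    }
    x <- Biostrings::DNAStringSet(toupper(x))
    freq <- Biostrings::alphabetFrequency(x)
    allowed <- c("A", "C", "G", "T", "N")
    other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
    if (any(other > 0))
        stop("non-ACGTN characters in record(s): ",
             paste(names(x)[other > 0], collapse = ", "))
    x
}

#' Write a genome collection to FASTA
#'
#' @param genomes a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
writeGenomes <- function(genomes, path, width = 80L) {
    Biostrings::writeXStringSet(genomes, path, width = width)
    invisible(path)
}

#' Validate a labelled distance matrix
#'
#' Checks the invariants shared by every distance matrix in the pipeline
#' (Mash, ANI and Jaccard distances alike): square and numeric with matching
#' row/column labels, symmetric to `tol`, zero diagonal, entries in `[0, 1]`.
#'
#' @param m a numeric matrix with dimnames.
#' @param tol asymmetry tolerance (default 1e-9).
#' @return `m`, with the symmetric part enforced exactly
#'   (`(m + t(m)) / 2`) and the diagonal set to 0.
#' @export
validateDistanceMatrix <- function(m, tol = 1e-9) {
    if (!is.matrix(m) || !is.numeric(m)) stop("not a numeric matrix")
    if (nrow(m) != ncol(m)) stop("distance matrix is not square")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("distance matrix must have row and column labels")
    if (!identical(rownames(m), colnames(m)))
        stop("row and column labels differ")
    if (anyNA(m)) stop("distance matrix contains NA")
    if (any(m < 0)) stop("negative distances")
    if (max(abs(m - t(m))) > tol)
        stop("distance matrix asymmetric beyond tolerance ", tol)
    if (max(abs(diag(m))) > tol)
        stop("distance matrix diagonal is not zero")
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
}

#' Read / write a distance matrix as TSV
#'
#' The on-disk dialect is fixed so matrices round-trip byte-for-byte: tab
#' separated, UNIX newlines, '.' decimal separator, full `%.17g` precision,
#' a header row of labels and a first label column.
#'
#' @param path file path.
#' @return `readDistanceMatrix`: a validated numeric matrix with dimnames.
#' @seealso [validateDistanceMatrix()]
#' @export
readDistanceMatrix <- function(path) {
    if (!file.exists(path)) stop("matrix file not found: ", path)
    df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                     check.names = FALSE, colClasses = "character")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    validateDistanceMatrix(m)
}

#' @rdname readDistanceMatrix
#' @param m a labelled symmetric distance matrix.
#' @export
writeDistanceMatrix <- function(m, path) {
    m <- validateDistanceMatrix(m)
    con <- file(path, open = "wb")  # binary: UNIX newlines on any platform
    on.exit(close(con))
    writeLines(paste(c("", colnames(m)), collapse = "\t"), con, sep = "\n")
    for (i in seq_len(nrow(m))) {
        writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                         collapse = "\t"), con, sep = "\n")
    }
    invisible(path)
}
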