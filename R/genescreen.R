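#' Read blast-style tabular homology hits
#'
#' Parses the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' as emitted by blast or diamond, and joins per-query lengths either from a
#' 13th column (`qlen`) or from a supplied named vector (e.g. widths of the
#' predicted-gene FASTA).
#'
#' @param path tabular hits file (no header).
#' @param queryLengths optional named numeric vector, query id -> length;
#'   required when the file has only 12 columns.
#' @return A `data.frame` of hits with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `evalue`, `bitscore`, `query_length`.
#' @export
readHits <- function(path, queryLengths = NULL) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (!ncol(df) %in% c(12L, 13L))
        stop("expected 12 or 13 tab-separated columns, got ", ncol(df))
    out <- data.frame(query_id = as.character(df[[1]]),
                      subject_id = as.character(df[[2]]),
                      pct_identity = as.numeric(df[[3]]),
                      aln_length = as.numeric(df[[4]]),
                      evalue = as.numeric(df[[11]]),
                      bitscore = as.numeric(df[[12]]),
                      stringsAsFactors = FALSE)
    if (ncol(df) == 13L) {
        out$query_length <- as.numeric(df[[13]])
    } else {
        if (is.null(queryLengths))
            stop("12-column input needs queryLengths")
        out$query_length <- unname(queryLengths[out$query_id])
    }
    bad <- unique(out$query_id[is.na(out$query_length)])
    if (length(bad))
        stop("missing query length for: ", paste(bad, collapse = ", "))
    out
}

#' Filter homology hits
#'
#' Applies the screening thresholds: e-value at most `maxEvalue`
#' (inclusive), identity strictly above `minIdentityPct`, and alignment
#' covering at least `minQueryCov` of the query length (inclusive). When a
#' query retains several hits, only the best is kept: highest bitscore,
#' ties broken by lowest e-value, then lexicographic subject id.
#'
#' @param hits data.frame as returned by [readHits()] (columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `evalue`, `bitscore`,
#'   `query_length`).
#' @param config a [PipelineConfig-class] supplying the thresholds.
#' @param bestHitOnly keep one hit per query (default TRUE).
#' @return The retained subset, one row per query when `bestHitOnly`.
#' @export
filterHits <- function(hits, config = pipelineConfig(), bestHitOnly = TRUE) {
    bad <- unique(hits$query_id[is.na(hits$query_length)])
    if (length(bad))
        stop("missing query length for: ", paste(bad, collapse = ", "))
    keep <- hits$evalue <= config@maxEvalue &
        hits$pct_identity > config@minIdentityPct &
        hits$aln_length / hits$query_length >= config@minQueryCov
    out <- hits[keep, , drop = FALSE]
    if (bestHitOnly && nrow(out)) {
        ord <- order(out$query_id, -out$bitscore, out$evalue, out$subject_id)
        out <- out[ord, , drop = FALSE]
        out <- out[!duplicated(out$query_id), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' RPKM normalisation
#'
#' Reads per kilobase of gene per million mapped reads:
#' `RPKM_a = (c_a * 1e9) / (L_a * N)` with `c_a` reads mapped to gene `a`,
#' `L_a` the gene length in bases and `N` the total mapped reads of the
#' sample. The 1e9 factor is the kilobase x million scaling the unit's name
#' implies.
#'
#' @param counts named numeric vector, gene -> mapped-read count.
#' @param lengths named numeric vector, gene -> length in bases; must cover
#'   every counted gene.
#' @param totalMapped total mapped reads in the sample (`>= 1`).
#' @return Named numeric vector of RPKM values.
#' @examples
#' rpkm(c(geneA = 10), c(geneA = 1000), 1e6)  # 10
#' @export
rpkm <- function(counts, lengths, totalMapped) {
    if (totalMapped < 1) stop("totalMapped must be >= 1")
    if (any(lengths < 1)) stop("gene lengths must be >= 1")
    L <- lengths[names(counts)]
    bad <- names(counts)[is.na(L)]
    if (length(bad))
        stop("gene(s) with a count but no length: ",
             paste(bad, collapse = ", "))
    setNames(as.numeric(counts) * 1e9 / (as.numeric(L) * totalMapped),
             names(counts))
}

#' Per-sample RPKM table from a count matrix
#'
#' @param countMatrix genes x samples matrix of mapped-read counts.
#' @param lengths named numeric vector of gene lengths (bases).
#' @param totalMapped named numeric vector of per-sample total mapped reads;
#'   defaults to the column sums.
#' @return genes x samples matrix of RPKM values.
#' @export
rpkmTable <- function(countMatrix, lengths, totalMapped = NULL) {
    if (is.null(totalMapped)) totalMapped <- colSums(countMatrix)
    out <- vapply(seq_len(ncol(countMatrix)), function(j) {
        rpkm(setNames(countMatrix[, j], rownames(countMatrix)), lengths,
             totalMapped[j])
    }, numeric(nrow(countMatrix)))
    dimnames(out) <- dimnames(countMatrix)
    out
}

#' Collapse gene-level abundances to functional families
#'
#' Sums member-gene values per family and sample, so family totals conserve
#' the gene-level totals exactly. Families of the catalog with no retained
#' gene get a zero row.
#'
#' @param geneTable genes x samples numeric matrix (e.g. RPKM).
#' @param familyMap named character vector, gene id -> family label; must
#'   cover every row of `geneTable`.
#' @param allFamilies optional character vector of families to report
#'   (zero-filled when absent); default the families present in `familyMap`.
#' @return families x samples numeric matrix.
#' @export
familyAbundance <- function(geneTable, familyMap, allFamilies = NULL) {
    genes <- rownames(geneTable)
    fam <- familyMap[genes]
    bad <- genes[is.na(fam)]
    if (length(bad))
        stop("gene(s) not mapped to a family: ", paste(bad, collapse = ", "))
    if (is.null(allFamilies)) allFamilies <- sort(unique(unname(familyMap)))
    out <- matrix(0, length(allFamilies), ncol(geneTable),
                  dimnames = list(allFamilies, colnames(geneTable)))
    if (length(genes)) {
        agg <- rowsum(geneTable, group = unname(fam))
        out[rownames(agg), ] <- agg
    }
    out
}

#' Read a functional gene catalog
#'
#' TSV with header and columns `accession`, `family` (and optionally more);
#' returns the accession -> family map used by [familyAbundance()].
#'
#' @param path catalog TSV path.
#' @return Named character vector, accession -> family.
#' @export
readCatalog <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    if (!all(c("accession", "family") %in% colnames(df)))
        stop("catalog needs 'accession' and 'family' columns")
    if (anyDuplicated(df$accession))
        stop("duplicate accession in catalog")
    setNames(df$family, df$accession)
}
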