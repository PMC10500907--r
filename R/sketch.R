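#' MinHash bottom-sketch of a genome
#'
#' A bottom-s MinHash sketch: the `s` smallest hash values over the canonical
#' k-mers of one genome (canonical = the lexicographically smaller of a k-mer
#' and its reverse complement). Two sketches are comparable only when built
#' with identical `k`, `s` and `hashSeed`.
#'
#' Hash values are 53-bit truncations of a 64-bit mixed hash of the 2-bit
#' packed canonical k-mer, stored as doubles so they are exact in R; k-mers
#' containing N are skipped.
#'
#' @slot genomeId genome label.
#' @slot k k-mer size in bases.
#' @slot s sketch capacity.
#' @slot hashSeed seed of the hash function.
#' @slot hashes strictly increasing hash values, `length(hashes) ==
#'   min(s, number of distinct canonical k-mers)`.
#' @export
setClass("MinHashSketch",
    representation(genomeId = "character", k = "integer", s = "integer",
                   hashSeed = "integer", hashes = "numeric"))

setValidity("MinHashSketch", function(object) {
    msg <- character()
    if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
        msg <- c(msg, "genomeId must be a single non-empty string")
    if (length(object@hashes) == 0L)
        msg <- c(msg, "sketch has no hashes")
    if (length(object@hashes) > object@s)
        msg <- c(msg, "more hashes than sketch capacity s")
    if (is.unsorted(object@hashes, strictly = TRUE))
        msg <- c(msg, "hashes must be strictly increasing")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MinHashSketch", function(object) {
    cat("MinHashSketch of", object@genomeId,
        sprintf("(k = %d, s = %d, %d hashes)\n",
                object@k, object@s, length(object@hashes)))
})

#' Build a MinHash sketch
#'
#' @param genome a [Biostrings::DNAString], single-element
#'   [Biostrings::DNAStringSet], or character string.
#' @param genomeId label for the sketch; defaults to the element name when
#'   `genome` is a named `DNAStringSet`.
#' @param k k-mer size (default 21).
#' @param s sketch capacity (default 10000).
#' @param hashSeed hash-function seed (default 42); both members of a
#'   compared pair must use the same value.
#' @return A [MinHashSketch-class].
#' @examples
#' sk <- buildSketch("ACGTACGTACGTACGTACGTACGTACGT", genomeId = "g1", k = 4)
#' sk
#' @export
buildSketch <- function(genome, genomeId = NULL, k = 21L, s = 10000L,
                        hashSeed = 42L) {
    if (is(genome, "DNAStringSet")) {
        if (length(genome) != 1L)
            stop("buildSketch expects a single genome; got ", length(genome))
        if (is.null(genomeId)) genomeId <- names(genome)
        genome <- genome[[1L]]
    }
    seq <- as.character(genome)
    if (is.null(genomeId) || !length(genomeId)) genomeId <- "genome"
    if (nchar(seq) < k)
        stop("genome '", genomeId, "' is shorter than k = ", k)
    hashes <- sketch_hashes_cpp(seq, as.integer(k), as.integer(s),
                                as.double(hashSeed))
    new("MinHashSketch", genomeId = genomeId, k = as.integer(k),
        s = as.integer(s), hashSeed = as.integer(hashSeed), hashes = hashes)
}

#' Sketch every genome of a collection
#'
#' @param genomes a named [Biostrings::DNAStringSet].
#' @param config a [PipelineConfig-class]; supplies `k`, `s` and the hash
#'   seed.
#' @return A named list of [MinHashSketch-class] objects.
#' @export
buildSketches <- function(genomes, config = pipelineConfig()) {
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
        stop("genomes must be named")
    sk <- lapply(seq_along(genomes), function(i) {
        buildSketch(genomes[[i]], genomeId = names(genomes)[i],
                    k = config@kmerSize, s = config@sketchSize,
                    hashSeed = config@hashSeed)
    })
    names(sk) <- names(genomes)
    sk
}

.checkComparable <- function(a, b) {
    if (a@k != b@k || a@s != b@s || a@hashSeed != b@hashSeed)
        stop("sketches are not comparable: k/s/hashSeed differ (",
             a@genomeId, " vs ", b@genomeId, ")")
}

#' Jaccard similarity estimate from two bottom sketches
#'
#' Uses the union-bottom (Mash) estimator: with `X` the `s` smallest values
#' of the merged hash sets, the estimate is `|X n S(A) n S(B)| / |X|`. This
#' is the unbiased estimator for bottom sketches, not the naive
#' intersection-over-union of the two sketches.
#'
#' @param a,b [MinHashSketch-class] objects sharing `k`, `s` and hash seed.
#' @return Estimated Jaccard index in `[0, 1]`.
#' @export
jaccardEstimate <- function(a, b) {
    .checkComparable(a, b)
    x <- sort(unique(c(a@hashes, b@hashes)))
    if (length(x) > a@s) x <- x[seq_len(a@s)]
    shared <- a@hashes[match(a@hashes, b@hashes, nomatch = 0L) > 0L]
    sum(shared <= x[length(x)] & shared %in% x) / length(x)
}

#' Mash distance from a Jaccard estimate
#'
#' `d = -(1/k) * log(2 j / (1 + j))`, the Mash point estimate of per-site
#' divergence under a Poisson mutation model. `j = 1` gives 0; `j = 0` (and
#' any value the formula pushes above 1) saturates at 1.
#'
#' @param j Jaccard estimate in `[0, 1]`.
#' @param k k-mer size used for the sketches.
#' @return Distance in `[0, 1]`.
#' @examples
#' mashDistance(0.5, 21)  # 0.0193086...
#' @export
mashDistance <- function(j, k) {
    if (any(j < 0 | j > 1)) stop("Jaccard estimate outside [0, 1]")
    d <- ifelse(j == 0, 1, -(1 / k) * log(2 * j / (1 + j)))
    pmin(d, 1)
}

#' All-versus-all Mash distances
#'
#' Sketches every genome and fills a symmetric, zero-diagonal distance
#' matrix; each unordered pair is computed once.
#'
#' @param genomes a named [Biostrings::DNAStringSet] (>= 2 genomes), or a
#'   named list of prebuilt [MinHashSketch-class] objects.
#' @param config a [PipelineConfig-class].
#' @return A labelled symmetric distance matrix.
#' @export
pairwiseMash <- function(genomes, config = pipelineConfig()) {
    sketches <- if (is.list(genomes) && all(vapply(genomes, is, logical(1),
                                                   "MinHashSketch"))) {
        genomes
    } else {
        buildSketches(genomes, config)
    }
    n <- length(sketches)
    if (n < 2L) stop("need at least 2 genomes")
    ids <- unname(vapply(sketches, slot, character(1), "genomeId"))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
        for (jj in seq(i + 1L, n)) {
            d <- mashDistance(jaccardEstimate(sketches[[i]], sketches[[jj]]),
                              sketches[[i]]@k)
            m[i, jj] <- m[jj, i] <- d
        }
    }
    m
}

#' Read / write sketch collections as TSV
#'
#' One row per sketch: `genome_id`, `k`, `s`, `hash_seed`, and the
#' comma-joined hash values (integers, full precision).
#'
#' @param path file path.
#' @return `readSketches`: a named list of [MinHashSketch-class] objects.
#' @export
readSketches <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "integer",
                                    "integer", "character"))
    sk <- lapply(seq_len(nrow(df)), function(i) {
        new("MinHashSketch", genomeId = df$genome_id[i], k = df$k[i],
            s = df$s[i], hashSeed = df$hash_seed[i],
            hashes = as.numeric(strsplit(df$hashes[i], ",", fixed = TRUE)[[1]]))
    })
    names(sk) <- df$genome_id
    sk
}

#' @rdname readSketches
#' @param sketches a list of [MinHashSketch-class] objects.
#' @export
writeSketches <- function(sketches, path) {
    rows <- vapply(sketches, function(x) {
        paste(x@genomeId, x@k, x@s, x@hashSeed,
              paste(sprintf("%.0f", x@hashes), collapse = ","), sep = "\t")
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("genome_id\tk\ts\thash_seed\thashes", rows), con, sep = "\n")
    invisible(path)
}
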