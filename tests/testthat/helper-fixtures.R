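# Shared fixtures: independent oracles and planted-structure builders.

# Brute-force canonical k-mer set of a sequence (independent of the C++
# sketching path): all k-substrings, reverse-complemented via Biostrings,
# lexicographic min per window, windows containing N dropped.
canonicalKmerSet <- function(seq, k) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    kmers <- substring(seq, seq_len(n - k + 1L), k:n)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
    unique(pmin(kmers, rc))
}

# Exact Jaccard index of two canonical k-mer sets (brute force).
exactKmerJaccard <- function(seqA, seqB, k) {
    a <- canonicalKmerSet(seqA, k)
    b <- canonicalKmerSet(seqB, k)
    length(intersect(a, b)) / length(union(a, b))
}

# Labelled symmetric matrix from an upper-triangle filler function.
buildDistMatrix <- function(n, fill, labels = paste0("g", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) m[i, j] <- m[j, i] <- fill(i, j)
    }
    m
}

# Planted k-cluster distance matrix with iid within-cluster noise: the
# regime in which prediction strength has its textbook behaviour.
plantedClusterMatrix <- function(kTrue, perCluster, seed,
                                 within = c(0.002, 0.008), between = 0.03,
                                 betweenJitter = 0.002) {
    n <- kTrue * perCluster
    lab <- rep(seq_len(kTrue), each = perCluster)
    set.seed(seed)
    buildDistMatrix(n, function(i, j) {
        if (lab[i] == lab[j]) runif(1, within[1], within[2])
        else between + runif(1, -betweenJitter, betweenJitter)
    })
}

plantedLabels <- function(kTrue, perCluster) rep(seq_len(kTrue), each = perCluster)

# Direct-construction sketch for estimator unit tests.
rawSketch <- function(hashes, k = 4L, s = 4L, id = "x", hashSeed = 1L) {
    new("MinHashSketch", genomeId = id, k = as.integer(k), s = as.integer(s),
        hashSeed = as.integer(hashSeed), hashes = as.numeric(hashes))
}

# Adjusted Rand index between two labelings (mclust's reference
# implementation serves as the independent scorer).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
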