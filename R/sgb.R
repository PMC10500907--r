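#' Dereplicate genomes into species-level genome bins
#'
#' Average-linkage agglomerative clustering of a genome distance matrix, cut
#' at `threshold` (default 0.05, the species-level genome bin cut): two
#' genomes share a bin when their clusters merged at height <= `threshold`.
#' Bin ids are renumbered 1..n_bins in order of first appearance in the
#' matrix labels, so the labelling is deterministic.
#'
#' @param m a labelled symmetric distance matrix (see
#'   [validateDistanceMatrix()]).
#' @param threshold distance cut in (0, 1).
#' @param linkage linkage method passed to [stats::hclust()]; average
#'   linkage is the default used throughout.
#' @return Named integer vector: genome id -> SGB id.
#' @examples
#' m <- matrix(c(0, .01, .2, .01, 0, .2, .2, .2, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' clusterSGBs(m, 0.05)
#' @export
clusterSGBs <- function(m, threshold = 0.05, linkage = "average") {
    if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
    m <- validateDistanceMatrix(m)
    n <- nrow(m)
    if (n < 2L) return(setNames(rep(1L, n), rownames(m)))
    hc <- hclust(as.dist(m), method = linkage)
    raw <- cutree(hc, h = threshold)
    # renumber by first appearance
    first <- raw[!duplicated(raw)]
    setNames(match(raw, first), rownames(m))
}

#' Rank bin for a nearest-reference distance
#'
#' Half-open rank bins on the nearest-reference Mash distance: species
#' (`d < 0.05`), genus (`[0.05, 0.15)`), family (`[0.15, 0.25)`), phylum
#' (`>= 0.25`), with the cut points taken from `config`.
#'
#' @param d nearest-reference distance(s) in `[0, 1]`.
#' @param config a [PipelineConfig-class].
#' @return Character vector over `{"species","genus","family","phylum"}`.
#' @export
assignRank <- function(d, config = pipelineConfig()) {
    if (any(d < 0 | d > 1)) stop("distance outside [0, 1]")
    ifelse(d < config@sgbThreshold, "species",
    ifelse(d < config@genusThreshold, "genus",
    ifelse(d < config@familyThreshold, "family", "phylum")))
}

#' Classify genomes against a reference sketch collection
#'
#' Nearest-neighbour placement: each query genome is compared with every
#' reference sketch; the smallest Mash distance decides whether the genome
#' falls in a known species-level bin (`d <` the 5% cut) and at which rank
#' an unknown genome is placed. Queries are never co-clustered with the
#' references, so the result does not depend on reference-set size beyond
#' the nearest neighbour. Distance ties are broken by lexicographic
#' reference id.
#'
#' @param sketches named list of query [MinHashSketch-class] objects (or a
#'   named `DNAStringSet`, sketched with `config`).
#' @param refSketches non-empty named list of reference sketches (or a named
#'   `DNAStringSet`).
#' @param config a [PipelineConfig-class].
#' @return A `data.frame` with columns `genome_id`, `known`,
#'   `nearest_ref_id`, `nearest_ref_distance`, `assigned_rank`.
#' @export
classifyGenomes <- function(sketches, refSketches,
                            config = pipelineConfig()) {
    toSketches <- function(x) {
        if (is(x, "DNAStringSet")) buildSketches(x, config) else x
    }
    sketches <- toSketches(sketches)
    refSketches <- toSketches(refSketches)
    if (!length(refSketches)) stop("empty reference collection")
    refIds <- vapply(refSketches, slot, character(1), "genomeId")
    ord <- order(refIds)  # lexicographic tie-break via stable which.min
    refSketches <- refSketches[ord]
    refIds <- refIds[ord]
    rows <- lapply(sketches, function(q) {
        d <- vapply(refSketches, function(r)
            mashDistance(jaccardEstimate(q, r), q@k), numeric(1))
        i <- which.min(d)
        data.frame(genome_id = q@genomeId,
                   known = d[i] < config@sgbThreshold,
                   nearest_ref_id = refIds[i],
                   nearest_ref_distance = unname(d[i]),
                   assigned_rank = assignRank(d[i], config),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarise species-level genome bins
#'
#' Per-bin member counts, known/unknown status and contributing sample
#' groups, plus collection-level totals of genomes in known vs unknown bins.
#' A bin drawing members from a single group is flagged as exclusive to it
#' (e.g. a bin found only in polyethylene-fed samples).
#'
#' @param sgbIds named integer vector, genome id -> SGB id (from
#'   [clusterSGBs()]).
#' @param known named logical vector, genome id -> known flag (from
#'   [classifyGenomes()]); a bin is known when any member is known.
#' @param groups named character vector, genome id -> sample group label.
#' @return A list with `perSGB` (data.frame: `sgb_id`, `n_members`, `known`,
#'   `groups`, `exclusive_group`) and `totals` (data.frame: counts and
#'   percentages of genomes in known/unknown bins).
#' @export
summarizeSGBs <- function(sgbIds, known, groups) {
    if (!length(sgbIds)) {
        return(list(
            perSGB = data.frame(sgb_id = integer(), n_members = integer(),
                                known = logical(), groups = character(),
                                exclusive_group = character(),
                                stringsAsFactors = FALSE),
            totals = data.frame(class = c("kSGB", "uSGB"), n_genomes = c(0L, 0L),
                                pct_genomes = c(NA_real_, NA_real_))))
    }
    ids <- names(sgbIds)
    missing <- setdiff(ids, names(groups))
    if (length(missing))
        stop("genome(s) missing a group label: ", paste(missing, collapse = ", "))
    missingK <- setdiff(ids, names(known))
    if (length(missingK))
        stop("genome(s) missing a known flag: ", paste(missingK, collapse = ", "))
    perSGB <- do.call(rbind, lapply(sort(unique(sgbIds)), function(b) {
        members <- ids[sgbIds == b]
        gr <- sort(unique(unname(groups[members])))
        data.frame(sgb_id = b, n_members = length(members),
                   known = any(known[members]),
                   groups = paste(gr, collapse = ","),
                   exclusive_group = if (length(gr) == 1L) gr else NA_character_,
                   stringsAsFactors = FALSE)
    }))
    binKnown <- setNames(perSGB$known, perSGB$sgb_id)
    genomeInKnown <- binKnown[as.character(sgbIds)]
    nk <- sum(genomeInKnown)
    nu <- sum(!genomeInKnown)
    totals <- data.frame(class = c("kSGB", "uSGB"),
                         n_genomes = c(nk, nu),
                         pct_genomes = 100 * c(nk, nu) / length(sgbIds))
    list(perSGB = perSGB, totals = totals)
}
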