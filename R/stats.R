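#' Binary Jaccard distance between samples
#'
#' Presence/absence transform (`value > 0`) of a samples x taxa abundance
#' table, then the Jaccard distance `1 - |intersection| / |union|` for every
#' sample pair (via [vegan::vegdist()] with `binary = TRUE`). Two samples
#' with no present taxa at all are at distance 0 by convention.
#'
#' @param table samples x taxa numeric matrix, non-negative, with sample
#'   rownames.
#' @return Labelled symmetric distance matrix.
#' @export
jaccardMatrix <- function(table) {
    if (nrow(table) < 2L) stop("need at least 2 samples")
    if (any(table < 0)) stop("abundances must be non-negative")
    # vegdist warns on all-absent rows; the 0-distance convention below
    # covers that case deliberately
    d <- as.matrix(suppressWarnings(
        vegan::vegdist(table > 0, method = "jaccard", binary = TRUE)))
    d[!is.finite(d)] <- 0  # pairs of all-absent samples
    validateDistanceMatrix(d)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor: the distance-based pseudo-F of Anderson's formulation, with
#' significance from `nPerm` random label permutations,
#' `p = (1 + #permuted F >= observed F) / (1 + nPerm)`. Delegates to
#' [vegan::adonis2()] under a fixed RNG seed so runs replay exactly.
#'
#' @param m labelled symmetric distance matrix over samples.
#' @param groups named character/factor vector, sample -> group; every group
#'   needs `>= 2` samples.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A list with `pseudo_F`, `R2`, `p_value`, `n_permutations`.
#' @export
permanova <- function(m, groups, nPerm = 999L, seed = 1L) {
    m <- validateDistanceMatrix(m)
    g <- groups[rownames(m)]
    if (anyNA(g))
        stop("group label missing for sample(s): ",
             paste(rownames(m)[is.na(g)], collapse = ", "))
    g <- factor(unname(g))
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
    set.seed(seed)
    fit <- vegan::adonis2(as.dist(m) ~ g, permutations = nPerm)
    list(pseudo_F = fit$F[1L], R2 = fit$R2[1L],
         p_value = fit[["Pr(>F)"]][1L], n_permutations = as.integer(nPerm))
}

#' Alpha-diversity indices per sample
#'
#' Observed richness, Shannon entropy (natural log), Gini-Simpson index and
#' Pielou evenness (`H / ln(richness)`, undefined and reported `NA` for
#' richness < 2). All-zero samples get `NA` indices with a warning.
#'
#' @param table samples x taxa numeric matrix, non-negative.
#' @return data.frame with columns `sample`, `richness`, `shannon`,
#'   `simpson`, `pielou`.
#' @export
alphaDiversity <- function(table) {
    if (any(table < 0)) stop("abundances must be non-negative")
    tot <- rowSums(table)
    if (any(tot == 0))
        warning("all-zero sample(s): ",
                paste(rownames(table)[tot == 0], collapse = ", "),
                "; indices reported as NA")
    rich <- as.integer(rowSums(table > 0))
    H <- suppressWarnings(vegan::diversity(table, index = "shannon"))
    S <- suppressWarnings(vegan::diversity(table, index = "simpson"))
    H[tot == 0] <- NA_real_
    S[tot == 0] <- NA_real_
    pielou <- ifelse(rich >= 2, H / log(rich), NA_real_)
    data.frame(sample = rownames(table), richness = rich, shannon = unname(H),
               simpson = unname(S), pielou = unname(pielou),
               stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon rank-sum tests between groups
#'
#' Two-sided unpaired Mann-Whitney tests for every pair of groups (exact
#' null when both sizes allow and there are no ties, normal approximation
#' with tie correction otherwise, as in [stats::wilcox.test()]), with
#' Benjamini-Hochberg adjusted p-values alongside the raw ones. Degenerate
#' comparisons where all values are equal return p = 1 with a warning.
#'
#' @param values named numeric vector, one value per sample.
#' @param groups named character/factor vector, sample -> group; each group
#'   needs `>= 2` samples.
#' @param adjust multiplicity adjustment method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return data.frame with columns `group1`, `group2`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwiseWilcoxon <- function(values, groups, adjust = "BH") {
    g <- factor(groups[names(values)])
    if (anyNA(g)) stop("group label missing for some samples")
    if (any(table(g) < 2L)) stop("every group needs at least 2 samples")
    lv <- levels(g)
    pairs <- combn(lv, 2L)
    p <- apply(pairs, 2L, function(pr) {
        x <- values[g == pr[1L]]
        y <- values[g == pr[2L]]
        if (length(unique(c(x, y))) == 1L) {
            warning("all values equal for ", pr[1L], " vs ", pr[2L],
                    "; p = 1")
            return(1.0)
        }
        suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
    })
    data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_value = p,
               p_adjusted = p.adjust(p, method = adjust),
               stringsAsFactors = FALSE)
}
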