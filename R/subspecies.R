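#' Fragment-based average nucleotide identity
#'
#' Estimates ANI between two genomes of one species-level bin: the query is
#' cut into non-overlapping fragments of `fragmentLen` bases, each fragment
#' is placed in the target at its best exact-match seed (15-mers) and scored
#' by ungapped identity over the full fragment; fragments reaching the 0.75
#' identity floor are retained and ANI is their mean identity. The estimate
#' is directional (the query is fragmented), so pipelines symmetrise it with
#' [aniDistanceMatrix()].
#'
#' @param query,target [Biostrings::DNAString] / single `DNAStringSet`
#'   element / character sequences, both at least `fragmentLen` long.
#' @param fragmentLen fragment length in bases (default 1000).
#' @param minIdentity per-fragment identity floor for retention (default
#'   0.75).
#' @return A list with `ani`, `n_fragments_used`, `n_fragments_total`.
#'   Errors when no fragment is retained (unalignable pair).
#' @export
fragmentANI <- function(query, target, fragmentLen = 1000L,
                        minIdentity = 0.75) {
    qs <- as.character(if (is(query, "DNAStringSet")) query[[1]] else query)
    ts <- as.character(if (is(target, "DNAStringSet")) target[[1]] else target)
    ids <- ani_fragment_identities_cpp(qs, ts, as.integer(fragmentLen))
    used <- ids[ids >= minIdentity]
    if (!length(used))
        stop("undefined ANI: no fragment reached identity ", minIdentity)
    list(ani = mean(used), n_fragments_used = length(used),
         n_fragments_total = length(ids))
}

#' Symmetrised ANI distance matrix for one SGB
#'
#' Computes directional ANI both ways for every genome pair and averages the
#' two directions; the distance is `1 - ANI`. Pairs for which neither
#' direction yields a retained fragment are set to the saturation distance
#' `1 - minIdentity` (maximally distant at the resolution of the estimator)
#' with a warning.
#'
#' @param genomes named [Biostrings::DNAStringSet] of the bin members.
#' @param fragmentLen fragment length in bases.
#' @param minIdentity per-fragment identity floor.
#' @return Labelled symmetric distance matrix with zero diagonal.
#' @export
aniDistanceMatrix <- function(genomes, fragmentLen = 1000L,
                              minIdentity = 0.75) {
    n <- length(genomes)
    if (n < 2L) stop("need at least 2 genomes")
    ids <- names(genomes)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    oneWay <- function(i, j) {
        tryCatch(fragmentANI(genomes[[i]], genomes[[j]], fragmentLen,
                             minIdentity)$ani,
                 error = function(e) NA_real_)
    }
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            a <- c(oneWay(i, j), oneWay(j, i))
            if (all(is.na(a))) {
                warning("undefined ANI for pair ", ids[i], " / ", ids[j],
                        "; set to saturation distance ", 1 - minIdentity)
                d <- 1 - minIdentity
            } else {
                d <- 1 - mean(a, na.rm = TRUE)
            }
            m[i, j] <- m[j, i] <- d
        }
    }
    m
}

#' Partitioning around medoids on a distance matrix
#'
#' k-medoids clustering (BUILD then SWAP, via [cluster::pam()]), returning
#' medoids, labels and the summed point-to-medoid cost. Deterministic for a
#' given matrix. The degenerate `k = n` case (every point its own medoid,
#' cost 0) is handled directly.
#'
#' @param m labelled symmetric distance matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @return List with `medoids` (indices), `medoid_ids` (labels), `labels`
#'   (named integer cluster assignment) and `cost`.
#' @export
pamCluster <- function(m, k) {
    m <- validateDistanceMatrix(m)
    n <- nrow(m)
    if (k < 1L || k > n) stop("k must be in [1, n]")
    if (k == n) {
        return(list(medoids = seq_len(n), medoid_ids = rownames(m),
                    labels = setNames(seq_len(n), rownames(m)), cost = 0))
    }
    fit <- cluster::pam(as.dist(m), k = k, diss = TRUE, keep.diss = FALSE,
                        keep.data = FALSE)
    med <- fit$id.med
    lab <- setNames(as.integer(fit$clustering), rownames(m))
    cost <- sum(vapply(seq_len(n), function(i) m[i, med[lab[i]]], numeric(1)))
    list(medoids = med, medoid_ids = rownames(m)[med], labels = lab,
         cost = cost)
}

.nearestMedoid <- function(m, points, medoids) {
    vapply(points, function(p) {
        d <- m[p, medoids]
        which.min(d)  # lowest index wins on ties
    }, integer(1))
}

#' Prediction strength of a k-clustering
#'
#' Cross-validated cluster-stability statistic: for each random 50/50 split,
#' both halves are PAM-clustered with `k` clusters; test points are then
#' classified to their nearest training medoid, and for every test cluster
#' the proportion of its point pairs co-assigned by the training classifier
#' is computed. The split score is the minimum proportion over test
#' clusters (singleton clusters score 1), and the returned value is the
#' mean over `nSplits` splits. `k = 1` is defined as 1. Values >= 0.8
#' conventionally support `k` as a real cluster number.
#'
#' @param m labelled symmetric distance matrix, `n >= 4` for `k >= 2`.
#' @param k candidate number of clusters, strictly below `floor(n/2)`.
#' @param nSplits number of random splits (default 50).
#' @param seed RNG seed for the splits.
#' @return Mean prediction strength in `[0, 1]`.
#' @export
predictionStrength <- function(m, k, nSplits = 50L, seed = 1L) {
    m <- validateDistanceMatrix(m)
    n <- nrow(m)
    if (k == 1L) return(1.0)
    if (n < 4L) stop("need n >= 4 for k >= 2")
    half <- n %/% 2L
    if (k >= half)
        stop("k must be below half the sample size (clusters of the halves ",
             "would be singletons)")
    set.seed(seed)
    scores <- vapply(seq_len(nSplits), function(i) {
        test <- sort(sample.int(n, half))
        train <- setdiff(seq_len(n), test)
        trainFit <- pamCluster(m[train, train, drop = FALSE], k)
        testFit <- pamCluster(m[test, test, drop = FALSE], k)
        trainMed <- train[trainFit$medoids]
        assigned <- .nearestMedoid(m, test, trainMed)
        clusterScores <- vapply(seq_len(k), function(cl) {
            members <- which(testFit$labels == cl)
            nc <- length(members)
            if (nc < 2L) return(1.0)
            a <- assigned[members]
            # pairs co-assigned by the training classifier
            same <- sum(outer(a, a, "==")) - nc
            same / (nc * (nc - 1L))
        }, numeric(1))
        min(clusterScores)
    }, numeric(1))
    mean(scores)
}

#' Subspecies detection result
#'
#' @slot sgbId label of the species-level bin analysed.
#' @slot psByK named numeric: mean prediction strength per candidate k.
#' @slot chosenK selected number of subspecies (1 = no substructure).
#' @slot labels named integer subspecies assignment per genome.
#' @slot medoidIds medoid genome ids of the final clustering.
#' @export
setClass("SubspeciesResult",
    representation(sgbId = "character", psByK = "numeric",
                   chosenK = "integer", labels = "integer",
                   medoidIds = "character"))

setValidity("SubspeciesResult", function(object) {
    msg <- character()
    if (object@chosenK < 1L) msg <- c(msg, "chosenK must be >= 1")
    if (length(unique(object@labels)) != object@chosenK)
        msg <- c(msg, "number of distinct labels must equal chosenK")
    if (length(object@medoidIds) != object@chosenK)
        msg <- c(msg, "one medoid per cluster required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SubspeciesResult", function(object) {
    cat("SubspeciesResult for", object@sgbId, "\n")
    cat("  chosen k =", object@chosenK, "\n")
    cat("  prediction strength by k:",
        paste(sprintf("k=%s: %.3f", names(object@psByK), object@psByK),
              collapse = ", "), "\n")
    cat("  cluster sizes:",
        paste(table(object@labels), collapse = ", "), "\n")
})

#' Select the number of subspecies in an SGB
#'
#' Evaluates candidate cluster numbers `k = 1..kMax` by prediction strength
#' on the symmetrised ANI distance matrix and selects the largest `k` whose
#' mean prediction strength meets the support threshold (default 0.8);
#' `k = 1` (always supported) means no subspecies structure. Final labels
#' and medoids come from PAM on the full matrix at the chosen k.
#'
#' @param m symmetrised ANI distance matrix of one SGB.
#' @param kMax largest candidate k; default `min(8, floor(n/2))`.
#' @param config a [PipelineConfig-class] (supplies the support threshold
#'   and default seed).
#' @param nSplits prediction-strength splits per k (default 50).
#' @param seed RNG seed; defaults to `config@rngSeed`.
#' @param sgbId label stored in the result.
#' @return A [SubspeciesResult-class].
#' @export
selectSubspecies <- function(m, kMax = NULL, config = pipelineConfig(),
                             nSplits = 50L, seed = NULL, sgbId = "SGB") {
    m <- validateDistanceMatrix(m)
    n <- nrow(m)
    if (is.null(kMax)) kMax <- min(8L, n %/% 2L)
    # prediction strength needs k strictly below the half-sample size
    kMax <- max(1L, min(kMax, n %/% 2L - 1L))
    if (is.null(seed)) seed <- config@rngSeed
    ks <- seq_len(kMax)
    ps <- vapply(ks, function(k)
        predictionStrength(m, k, nSplits = nSplits, seed = seed), numeric(1))
    names(ps) <- ks
    supported <- ks[ps >= config@psThreshold]
    chosenK <- if (length(supported)) max(supported) else 1L
    fit <- pamCluster(m, chosenK)
    new("SubspeciesResult", sgbId = sgbId, psByK = ps,
        chosenK = as.integer(chosenK), labels = fit$labels,
        medoidIds = fit$medoid_ids)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Metric MDS by eigendecomposition of the double-centred squared-distance
#' matrix ([stats::cmdscale()]), with axes ordered by decreasing eigenvalue
#' and a deterministic sign convention: the first coordinate of each axis
#' whose magnitude exceeds 1e-12 is made positive. Axes for non-positive
#' eigenvalues are dropped; if fewer than `dims` remain, the available ones
#' are returned with a warning.
#'
#' @param m labelled symmetric distance matrix.
#' @param dims requested embedding dimension (default 2), `<= n - 1`.
#' @return Numeric matrix (n x `<= dims`) of coordinates, rownames = labels.
#' @export
classicalMDS <- function(m, dims = 2L) {
    m <- validateDistanceMatrix(m)
    n <- nrow(m)
    if (dims > n - 1L) stop("dims must be <= n - 1")
    if (max(m) == 0)  # coincident points: zero configuration in any dims
        return(matrix(0, n, dims, dimnames = list(rownames(m), NULL)))
    fit <- cmdscale(as.dist(m), k = min(dims, n - 1L), eig = TRUE)
    pos <- sum(fit$eig > 1e-12)
    keep <- min(dims, pos)
    if (keep < dims)
        warning("only ", keep, " positive eigenvalue(s); returning ", keep,
                " dimension(s)")
    if (keep == 0L)
        return(matrix(0, n, 0, dimnames = list(rownames(m), NULL)))
    coords <- fit$points[, seq_len(keep), drop = FALSE]
    for (a in seq_len(ncol(coords))) {
        nz <- which(abs(coords[, a]) > 1e-12)
        if (length(nz) && coords[nz[1L], a] < 0)
            coords[, a] <- -coords[, a]
    }
    rownames(coords) <- rownames(m)
    coords
}
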