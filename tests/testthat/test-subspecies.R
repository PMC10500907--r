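test_that("fragment ANI is exact for identical genomes and tracks divergence", {
    g <- randomGenome(50000, seed = 31)
    res <- fragmentANI(g, g, fragmentLen = 1000)
    expect_equal(res$ani, 1.0)
    expect_equal(res$n_fragments_used, res$n_fragments_total)
    expect_equal(res$n_fragments_total, 50L)

    # 2% substitution: expected identity 0.98 (500 kb, all fragments align)
    for (seed in 1:3) {
        q <- randomGenome(5e5, seed = 3100 + seed)
        t2 <- evolveGenome(q, 0.02, seed = 3200 + seed)
        a <- fragmentANI(q, t2, fragmentLen = 1000)
        expect_gt(a$ani, 0.975)
        expect_lt(a$ani, 0.985)
        expect_equal(a$n_fragments_used, a$n_fragments_total)
    }
})

test_that("unrelated genomes yield an undefined-ANI error", {
    # accidental shared 15-mers between independent 100 kb sequences place
    # a few fragments, but none can reach the 0.75 identity floor
    for (seed in 1:3) {
        a <- randomGenome(1e5, seed = 4100 + seed)
        b <- randomGenome(1e5, seed = 4200 + seed)
        expect_error(fragmentANI(a, b, fragmentLen = 1000), "undefined ANI")
    }
})

test_that("the symmetrised ANI matrix separates planted subspecies", {
    sim <- simulateCommunity(1, 8, subspecies = list(k = 2, betweenDiv = 0.03,
                                                     withinDiv = 0.005),
                             genomeLen = 1e5, seed = 41)
    m <- aniDistanceMatrix(sim$genomes, fragmentLen = 1000)
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 8))
    same <- outer(sim$truth$subspecies, sim$truth$subspecies, "==")
    diag(same) <- NA
    expect_lt(max(m[which(same)]), 0.01)
    expect_gt(min(m[which(!same)]), 0.02)
})

test_that("PAM matches brute-force medoid search on separated groups", {
    lab <- rep(1:2, each = 3)
    set.seed(51)
    m <- buildDistMatrix(6, function(i, j)
        if (lab[i] == lab[j]) 0.01 + runif(1, 0, 0.002) else 0.5)

    # k = 1: medoid minimises the summed distance to all points
    f1 <- pamCluster(m, 1)
    sums <- rowSums(m)
    expect_equal(f1$medoids, unname(which.min(sums)))
    expect_equal(f1$cost, sum(m[, f1$medoids]) )

    # k = 2: planted bipartition, cost equal to the exhaustive minimum
    # over all 15 medoid pairs
    f2 <- pamCluster(m, 2)
    expect_equal(ari(f2$labels, lab), 1)
    pairCosts <- apply(combn(6, 2), 2, function(med)
        sum(apply(m[, med, drop = FALSE], 1, min)))
    expect_equal(f2$cost, min(pairCosts))

    # k = n: every point its own medoid, zero cost
    fn <- pamCluster(m, 6)
    expect_equal(fn$cost, 0)
    expect_equal(length(unique(fn$labels)), 6L)
    expect_error(pamCluster(m, 7), "k must be")
})

test_that("prediction strength separates planted clusters from noise", {
    expect_equal(predictionStrength(plantedClusterMatrix(2, 6, 1), 1), 1.0)

    # two well-separated clusters: near-perfect at k = 2 over 10 seeds
    for (s in 1:10) {
        m <- plantedClusterMatrix(2, 6, s, within = c(0, 0.01), between = 0.5)
        expect_gte(predictionStrength(m, 2, nSplits = 50, seed = s), 0.95)
    }

    # structureless distances: k = 4 unsupported in >= 9/10 seeds
    bad <- 0L
    for (s in 1:10) {
        set.seed(s)
        r <- buildDistMatrix(12, function(i, j) runif(1, 0.2, 0.8))
        if (predictionStrength(r, 4, nSplits = 50, seed = s) < 0.8)
            bad <- bad + 1L
    }
    expect_gte(bad, 9L)

    expect_error(predictionStrength(plantedClusterMatrix(2, 6, 1), 6),
                 "below half")
})

test_that("prediction strength collapses beyond the planted cluster number", {
    psk <- vapply(2:5, function(k) {
        mean(vapply(1:10, function(s)
            predictionStrength(plantedClusterMatrix(2, 6, s,
                                                    within = c(0, 0.01),
                                                    between = 0.5),
                               k, nSplits = 50, seed = s), numeric(1)))
    }, numeric(1))
    expect_gte(psk[1], 0.95)          # supported at the true k
    expect_lt(max(psk[-1]), 0.8)      # unsupported for every k > 2
    expect_lte(psk[2], psk[1])        # and drops immediately past k_true
})

test_that("the subspecies count is recovered across planted structures", {
    for (kTrue in 1:3) {
        hits <- sum(vapply(1:20, function(s) {
            m <- plantedClusterMatrix(kTrue, 6, s)
            res <- selectSubspecies(m, kMax = 5, seed = s,
                                    sgbId = sprintf("sgb_k%d", kTrue))
            res@chosenK == kTrue
        }, logical(1)))
        expect_gte(hits, 18L)  # >= 90% of 20 seeded runs
    }

    # result object invariants on a deterministic case
    m <- plantedClusterMatrix(2, 6, 99)
    res <- selectSubspecies(m, kMax = 5, seed = 99)
    expect_s4_class(res, "SubspeciesResult")
    expect_equal(res@chosenK, 2L)
    expect_gte(res@psByK[["2"]], 0.8)
    expect_equal(length(unique(res@labels)), 2L)
    expect_equal(length(res@medoidIds), 2L)
    expect_equal(ari(res@labels, plantedLabels(2, 6)), 1)
})

test_that("planted two-subspecies genomes support k = 2 at the 0.8 criterion", {
    sim <- simulateCommunity(1, 8, subspecies = list(k = 2, betweenDiv = 0.03,
                                                     withinDiv = 0.005),
                             genomeLen = 1e5, seed = 61)
    m <- aniDistanceMatrix(sim$genomes, fragmentLen = 1000)
    ps2 <- predictionStrength(m, 2, nSplits = 50, seed = 61)
    expect_gte(ps2, 0.8)
    fit <- pamCluster(m, 2)
    expect_equal(ari(fit$labels, sim$truth$subspecies), 1)
})

test_that("classical MDS reproduces known configurations", {
    # two points at distance d embed at +/- d/2
    m2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
    xy <- classicalMDS(m2, dims = 1)
    expect_equal(sort(unname(xy[, 1])), c(-0.2, 0.2), tolerance = 1e-12)
    expect_gt(xy[1, 1], 0)  # sign convention: first nonzero loading positive

    # Euclidean input: embedding distances match the input to 1e-9
    set.seed(71)
    pts <- matrix(runif(8), 4, 2)
    m4 <- as.matrix(dist(pts))
    dimnames(m4) <- list(paste0("p", 1:4), paste0("p", 1:4))
    emb <- classicalMDS(m4, dims = 2)
    expect_equal(as.matrix(dist(emb)), unname(m4) * 1, ignore_attr = TRUE,
                 tolerance = 1e-9)

    # coincident points embed at the origin
    z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    expect_equal(classicalMDS(z, dims = 2),
                 matrix(0, 3, 2, dimnames = list(letters[1:3], NULL)))

    expect_error(classicalMDS(m2, dims = 2), "dims")
    # rank-deficient input returns fewer axes with a warning
    line <- as.matrix(dist(cbind(c(0, 1, 2), 0)))
    dimnames(line) <- list(paste0("p", 1:3), paste0("p", 1:3))
    expect_warning(got <- classicalMDS(line, dims = 2), "positive eigen")
    expect_equal(ncol(got), 1L)
})
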