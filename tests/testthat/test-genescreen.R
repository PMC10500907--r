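mkHit <- function(query = "q1", subject = "s1", pident = 97, len = 300,
                  evalue = 1e-10, bits = 500, qlen = 500) {
    data.frame(query_id = query, subject_id = subject, pct_identity = pident,
               aln_length = len, evalue = evalue, bitscore = bits,
               query_length = qlen, stringsAsFactors = FALSE)
}

test_that("hit filtering applies the boundary semantics exactly", {
    cfg <- pipelineConfig()
    # identity 96, coverage 0.6, e = 1e-10: retained
    expect_equal(nrow(filterHits(mkHit(pident = 96, len = 300, qlen = 500),
                                 cfg)), 1L)
    # identity exactly 95: rejected (strictly greater than required)
    expect_equal(nrow(filterHits(mkHit(pident = 95), cfg)), 0L)
    expect_equal(nrow(filterHits(mkHit(pident = 95.01), cfg)), 1L)
    # coverage exactly 0.50: retained (at least half the query)
    expect_equal(nrow(filterHits(mkHit(len = 250, qlen = 500), cfg)), 1L)
    expect_equal(nrow(filterHits(mkHit(len = 249, qlen = 500), cfg)), 0L)
    # e-value exactly at the cutoff: retained
    expect_equal(nrow(filterHits(mkHit(evalue = 1e-5), cfg)), 1L)
    expect_equal(nrow(filterHits(mkHit(evalue = 1.1e-5), cfg)), 0L)
})

test_that("multi-hit queries keep the best hit by bitscore, evalue, subject", {
    hits <- rbind(mkHit(subject = "sB", bits = 400),
                  mkHit(subject = "sA", bits = 500),
                  mkHit(subject = "sC", bits = 500, evalue = 1e-12),
                  mkHit(query = "q2", subject = "sD"))
    out <- filterHits(hits, pipelineConfig())
    expect_equal(nrow(out), 2L)
    expect_equal(out$subject_id[out$query_id == "q1"], "sC")  # lowest evalue
    tie <- rbind(mkHit(subject = "zz"), mkHit(subject = "aa"))
    expect_equal(filterHits(tie, pipelineConfig())$subject_id, "aa")
})

test_that("relaxing any single threshold never shrinks the retained set", {
    set.seed(81)
    hits <- do.call(rbind, lapply(1:60, function(i) {
        mkHit(query = sprintf("q%d", i), pident = runif(1, 80, 100),
              len = sample(100:500, 1), evalue = 10^runif(1, -20, 0),
              qlen = 500)
    }))
    base <- pipelineConfig()
    n0 <- nrow(filterHits(hits, base, bestHitOnly = FALSE))
    relaxed <- list(pipelineConfig(minIdentityPct = 90),
                    pipelineConfig(minQueryCov = 0.3),
                    pipelineConfig(maxEvalue = 1e-3))
    for (cfg in relaxed)
        expect_gte(nrow(filterHits(hits, cfg, bestHitOnly = FALSE)), n0)
})

test_that("hit files parse with lengths from a 13th column or a FASTA", {
    row12 <- paste(c("q1", "s1", "97.0", "300", "5", "0", "1", "300", "1",
                     "300", "1e-10", "500"), collapse = "\t")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(row12, f)
    expect_error(readHits(f), "queryLengths")
    hits <- readHits(f, queryLengths = c(q1 = 500))
    expect_equal(hits$query_length, 500)
    expect_equal(hits$bitscore, 500)
    writeLines(paste(row12, "480", sep = "\t"), f)
    expect_equal(readHits(f)$query_length, 480)
    writeLines(row12, f)
    expect_error(readHits(f, queryLengths = c(other = 1)), "q1")
})

test_that("RPKM follows its definition and invariances", {
    expect_equal(rpkm(c(g = 10), c(g = 1000), 1e6), c(g = 10))
    expect_equal(rpkm(c(g = 0), c(g = 1000), 1e6), c(g = 0))
    # doubling all counts and the library size changes nothing
    counts <- c(a = 14, b = 200, c = 0)
    lens <- c(a = 900, b = 1500, c = 700)
    expect_equal(rpkm(2 * counts, lens, 2e6), rpkm(counts, lens, 1e6))
    expect_error(rpkm(c(a = 1, zz = 2), lens, 1e6), "zz")
    expect_error(rpkm(counts, lens, 0), "totalMapped")
})

test_that("family collapse conserves per-sample totals exactly", {
    rt <- matrix(c(1.5, 2.5, 3.0, 0.5, 1.0, 2.0), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
    fam <- c(g1 = "DyP", g2 = "DyP", g3 = "MCO")
    fa <- familyAbundance(rt, fam)
    expect_equal(fa["DyP", "s1"], 4.0)
    expect_equal(colSums(fa), colSums(rt))
    # a catalog family with no retained gene reports zero
    fa2 <- familyAbundance(rt, fam, allFamilies = c("DyP", "MCO", "AlkB"))
    expect_equal(unname(fa2["AlkB", ]), c(0, 0))
    expect_error(familyAbundance(rt, fam[-1]), "g1")
})

test_that("a planted 5x family enrichment is detected by the group test", {
    groups <- setNames(rep(c("PE", "STD"), c(14, 6)), sprintf("s%d", 1:20))
    flagged <- vapply(1:10, function(s) {
        sim <- simulateGeneCounts(c(DyP = 8, MCO = 6, AlkB = 6), groups,
                                  effects = list(PE = c(DyP = 5)), seed = s)
        rt <- rpkmTable(sim$counts, sim$lengths, sim$totalMapped)
        fa <- familyAbundance(rt, sim$familyMap)
        pairwiseWilcoxon(fa["DyP", ], groups)$p_value < 0.05
    }, logical(1))
    expect_gte(sum(flagged), 9L)

    # without an effect, false flags are rare (alpha control, 3 families)
    clean <- vapply(1:20, function(s) {
        sim <- simulateGeneCounts(c(DyP = 8, MCO = 6, AlkB = 6), groups,
                                  effects = list(), seed = 100 + s)
        rt <- rpkmTable(sim$counts, sim$lengths, sim$totalMapped)
        fa <- familyAbundance(rt, sim$familyMap)
        !any(vapply(rownames(fa), function(f)
            pairwiseWilcoxon(fa[f, ], groups)$p_value < 0.05, logical(1)))
    }, logical(1))
    expect_gte(sum(clean), 16L)
})

test_that("catalog files map accessions to families", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("accession\tfamily", "WP_1\tDyP", "WP_2\tMCO"), f)
    expect_equal(readCatalog(f), c(WP_1 = "DyP", WP_2 = "MCO"))
    writeLines(c("accession\tfamily", "WP_1\tDyP", "WP_1\tMCO"), f)
    expect_error(readCatalog(f), "duplicate")
})
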