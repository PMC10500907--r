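# Seeded generators that plant known species/subspecies structure, gene-count
# effects and group-level composition turnover, so every downstream claim of
# the pipeline can be checked against a recorded ground truth.

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

.BASES <- c("A", "C", "G", "T")

#' Random genome with controlled GC content
#'
#' i.i.d. bases with `P(G) + P(C) = gc`, symmetric within each pair.
#' Bit-reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param length genome length in bases (`>= 1`).
#' @param gc GC fraction in (0, 1) (default 0.5).
#' @param seed RNG seed.
#' @return A [Biostrings::DNAString].
#' @export
randomGenome <- function(length, gc = 0.5, seed = 1L) {
    if (length < 1) stop("length must be >= 1")
    if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- .withSeed(seed, sample(.BASES, length, replace = TRUE, prob = p))
    Biostrings::DNAString(paste(s, collapse = ""))
}

#' Evolve a genome by independent per-site substitution
#'
#' Each site mutates with probability `divergence` to one of the three other
#' bases, uniformly; length is preserved and there are no indels (which
#' keeps sketch- and ANI-level expectations analytic: the realised mismatch
#' fraction is Binomial(`length`, `divergence`)/`length` up to back
#' mutations along multi-step lineages).
#'
#' @param ancestor a [Biostrings::DNAString] (or character string).
#' @param divergence per-site substitution probability in `[0, 0.75)`.
#' @param seed RNG seed.
#' @return A [Biostrings::DNAString] of the same length.
#' @export
evolveGenome <- function(ancestor, divergence, seed = 1L) {
    if (divergence < 0 || divergence >= 0.75)
        stop("divergence must be in [0, 0.75)")
    s <- strsplit(as.character(ancestor), "", fixed = TRUE)[[1L]]
    if (divergence > 0) {
        .withSeed(seed, {
            hit <- which(runif(length(s)) < divergence)
            if (length(hit)) {
                shift <- sample.int(3L, length(hit), replace = TRUE)
                code <- match(s[hit], .BASES) - 1L
                s[hit] <- .BASES[((code + shift) %% 4L) + 1L]
            }
        })
    }
    Biostrings::DNAString(paste(s, collapse = ""))
}

#' Simulate a genome community with planted species/subspecies structure
#'
#' One ancestor per species is evolved from a shared root at
#' `speciesDiv / 2`, so between-species pairwise divergence is about
#' `speciesDiv`; leaves evolve from their (sub)species ancestor at half the
#' stated pairwise divergence. With `subspecies = list(k, betweenDiv,
#' withinDiv)` each species gains `k` subspecies ancestors at
#' `betweenDiv / 2` from the species ancestor, and leaves are spread evenly
#' over them. The planted truth (species and subspecies index per genome)
#' is returned alongside.
#'
#' @param nSpecies number of species.
#' @param genomesPerSpecies leaves per species.
#' @param speciesDiv target pairwise between-species divergence.
#' @param withinDiv target pairwise within-(sub)species divergence.
#' @param subspecies `NULL`, or `list(k =, betweenDiv =)` (optionally
#'   `withinDiv` overriding the leaf-level value within subspecies).
#' @param genomeLen genome length in bases (default 1e5).
#' @param gc GC fraction.
#' @param seed RNG seed; all internal branches derive their seeds from it.
#' @return List with `genomes` (named [Biostrings::DNAStringSet], ids like
#'   `"sp1.1_g2"` for species 1, subspecies 1, leaf 2) and `truth`
#'   (data.frame: `genome_id`, `species`, `subspecies`).
#' @export
simulateCommunity <- function(nSpecies, genomesPerSpecies, speciesDiv = 0.2,
                              withinDiv = 0.01, subspecies = NULL,
                              genomeLen = 1e5L, gc = 0.5, seed = 1L) {
    if (!is.null(subspecies)) {
        if (speciesDiv <= subspecies$betweenDiv)
            stop("speciesDiv must exceed the between-subspecies divergence")
        if (subspecies$betweenDiv <= withinDiv)
            stop("between-subspecies divergence must exceed withinDiv")
    }
    root <- randomGenome(genomeLen, gc, seed = seed)
    nextSeed <- seed * 1000L
    takeSeed <- function() {
        nextSeed <<- (nextSeed + 7919L) %% .Machine$integer.max
        nextSeed
    }
    seqs <- list()
    truth <- list()
    for (sp in seq_len(nSpecies)) {
        spAnc <- evolveGenome(root, speciesDiv / 2, seed = takeSeed())
        nSub <- if (is.null(subspecies)) 1L else subspecies$k
        subDiv <- if (is.null(subspecies)) 0 else subspecies$betweenDiv / 2
        leafDiv <- if (!is.null(subspecies) && !is.null(subspecies$withinDiv))
            subspecies$withinDiv / 2 else withinDiv / 2
        subAnc <- lapply(seq_len(nSub), function(ss) {
            if (subDiv == 0) spAnc else evolveGenome(spAnc, subDiv,
                                                     seed = takeSeed())
        })
        for (leaf in seq_len(genomesPerSpecies)) {
            ss <- ((leaf - 1L) %% nSub) + 1L
            id <- sprintf("sp%d.%d_g%d", sp, ss, leaf)
            seqs[[id]] <- evolveGenome(subAnc[[ss]], leafDiv,
                                       seed = takeSeed())
            truth[[id]] <- data.frame(genome_id = id, species = sp,
                                      subspecies = ss,
                                      stringsAsFactors = FALSE)
        }
    }
    genomes <- Biostrings::DNAStringSet(lapply(seqs, identity))
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    list(genomes = genomes, truth = truthDf)
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions, random strand, per-base substitution errors at
#' `errorRate`; the read count is `round(coverage * length / readLen)`.
#'
#' @param genome a [Biostrings::DNAString].
#' @param coverage target mean per-base depth.
#' @param readLen read length in bases (`<=` genome length).
#' @param errorRate per-base error probability (default 0).
#' @param seed RNG seed.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
simulateReads <- function(genome, coverage, readLen, errorRate = 0,
                          seed = 1L) {
    L <- length(genome)
    if (readLen > L) stop("readLen exceeds genome length")
    n <- round(coverage * L / readLen)
    g <- as.character(genome)
    reads <- .withSeed(seed, {
        starts <- sample.int(L - readLen + 1L, n, replace = TRUE)
        rc <- runif(n) < 0.5
        out <- substring(g, starts, starts + readLen - 1L)
        if (any(rc)) {
            out[rc] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(out[rc])))
        }
        if (errorRate > 0) {
            chars <- strsplit(out, "", fixed = TRUE)
            out <- vapply(chars, function(s) {
                hit <- which(runif(length(s)) < errorRate)
                if (length(hit)) {
                    shift <- sample.int(3L, length(hit), replace = TRUE)
                    code <- match(s[hit], .BASES) - 1L
                    s[hit] <- .BASES[((code + shift) %% 4L) + 1L]
                }
                paste(s, collapse = "")
            }, character(1))
        }
        out
    })
    names(reads) <- sprintf("read_%d", seq_along(reads))
    Biostrings::DNAStringSet(reads)
}

#' Simulate per-sample gene counts with planted group effects
#'
#' Gene-level mapped-read counts drawn negative-binomially around
#' `baseline * multiplier`, where the multiplier is 1 except for the
#' (group, family) pairs named in `effects`. Dispersion is fixed at
#' `size = 5`, the over-dispersion typical of metagenomic count data. Gene
#' lengths are drawn uniformly in 600-1500 bases and per-sample totals add
#' a constant 1e6 background of reads mapped elsewhere, so RPKM values are
#' well defined.
#'
#' @param families named integer vector: family label -> number of genes.
#' @param groups named character vector: sample -> group label.
#' @param effects list of per-group multiplier vectors, e.g.
#'   `list(PE = c(DyP = 5))`; missing entries default to 1.
#' @param baseline baseline negative-binomial mean per gene (default 50).
#' @param dispersion negative-binomial size parameter (default 5).
#' @param seed RNG seed.
#' @return List with `counts` (genes x samples), `lengths`, `totalMapped`,
#'   `familyMap` (gene -> family) and `truth` (the multiplier matrix).
#' @export
simulateGeneCounts <- function(families, groups, effects = list(),
                               baseline = 50, dispersion = 5, seed = 1L) {
    geneFam <- rep(names(families), times = families)
    genes <- sprintf("%s_gene%d", geneFam,
                     unlist(lapply(families, seq_len), use.names = FALSE))
    samples <- names(groups)
    mult <- matrix(1, length(families), length(samples),
                   dimnames = list(names(families), samples))
    for (g in names(effects)) {
        for (f in names(effects[[g]]))
            mult[f, groups == g] <- effects[[g]][[f]]
    }
    out <- .withSeed(seed, {
        lengths <- setNames(sample(600:1500, length(genes), replace = TRUE),
                            genes)
        counts <- matrix(0, length(genes), length(samples),
                         dimnames = list(genes, samples))
        for (j in seq_along(samples)) {
            mu <- baseline * mult[geneFam, j]
            counts[, j] <- if (baseline > 0)
                rnbinom(length(genes), mu = mu, size = dispersion)
            else 0
        }
        list(counts = counts, lengths = lengths)
    })
    totalMapped <- setNames(colSums(out$counts) + 1e6, samples)
    list(counts = out$counts, lengths = out$lengths,
         totalMapped = totalMapped,
         familyMap = setNames(geneFam, genes), truth = mult)
}

#' Simulate a grouped composition table with planted turnover
#'
#' The first group's taxa presence profile is Bernoulli(0.5); every further
#' group flips the presence state of its own random `turnover` fraction of
#' taxa. Each sample then flips every taxon independently with probability
#' `noise` (within-group presence noise, default 5%), and present taxa get
#' lognormal abundances.
#'
#' @param groupNames character vector of group labels (first = baseline).
#' @param nPerGroup samples per group (recycled).
#' @param nTaxa number of taxa.
#' @param turnover fraction of taxa flipped between the baseline and each
#'   other group, in `[0, 1]`.
#' @param noise within-group per-taxon flip probability (default 0.05).
#' @param seed RNG seed.
#' @return List with `table` (samples x taxa abundance matrix) and `groups`
#'   (named character vector sample -> group).
#' @export
simulateComposition <- function(groupNames, nPerGroup, nTaxa = 100L,
                                turnover = 0.3, noise = 0.05, seed = 1L) {
    if (turnover < 0 || turnover > 1) stop("turnover must be in [0, 1]")
    nPerGroup <- rep_len(nPerGroup, length(groupNames))
    .withSeed(seed, {
        base <- runif(nTaxa) < 0.5
        profiles <- list()
        profiles[[groupNames[1L]]] <- base
        for (g in groupNames[-1L]) {
            flip <- sample.int(nTaxa, round(turnover * nTaxa))
            pr <- base
            pr[flip] <- !pr[flip]
            profiles[[g]] <- pr
        }
        rows <- list()
        groups <- character()
        for (gi in seq_along(groupNames)) {
            g <- groupNames[gi]
            for (i in seq_len(nPerGroup[gi])) {
                pres <- profiles[[g]]
                flip <- runif(nTaxa) < noise
                pres[flip] <- !pres[flip]
                ab <- numeric(nTaxa)
                ab[pres] <- rlnorm(sum(pres), meanlog = 2, sdlog = 1)
                id <- sprintf("%s_%d", g, i)
                rows[[id]] <- ab
                groups[id] <- g
            }
        }
        tab <- do.call(rbind, rows)
        colnames(tab) <- sprintf("taxon%d", seq_len(nTaxa))
        list(table = tab, groups = groups)
    })
}
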