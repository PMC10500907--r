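#' Pipeline configuration
#'
#' Holds every tunable threshold of the strain-resolution pipeline in one
#' validated object, so a run can be replayed exactly from its logged
#' configuration.
#'
#' Distance thresholds follow the species-level genome bin (SGB) convention:
#' genomes within `sgbThreshold` (5%) Mash distance of each other belong to
#' one species-level bin; an unknown bin is placed at genus, family or phylum
#' rank according to `genusThreshold` (15%) and `familyThreshold` (25%).
#' Boundary values fall into the higher rank: the rank bins are the half-open
#' intervals `[0, 0.05)`, `[0.05, 0.15)`, `[0.15, 0.25)`, `[0.25, 1]`.
#'
#' @slot kmerSize k-mer length for MinHash sketching (bases, <= 32).
#' @slot sketchSize bottom-sketch capacity s (number of retained hashes).
#' @slot sgbThreshold Mash distance cut for species-level bins (fraction).
#' @slot genusThreshold upper Mash distance for genus-level placement.
#' @slot familyThreshold upper Mash distance for family-level placement.
#' @slot psThreshold minimum mean prediction strength supporting k > 1
#'   subspecies clusters.
#' @slot minIdentityPct homology-hit identity floor, strict (percent).
#' @slot minQueryCov minimum alignment-length / query-length fraction.
#' @slot maxEvalue maximum hit e-value (inclusive).
#' @slot aniFragmentLen fragment length for fragment-based ANI (bases).
#' @slot nPermutations PERMANOVA permutation count.
#' @slot hashSeed seed of the k-mer hash function (not an RNG seed; both
#'   sketches of a compared pair must share it).
#' @slot rngSeed default seed for stochastic steps (splits, permutations).
#'
#' @export
setClass("PipelineConfig",
    representation(
        kmerSize = "integer", sketchSize = "integer",
        sgbThreshold = "numeric", genusThreshold = "numeric",
        familyThreshold = "numeric", psThreshold = "numeric",
        minIdentityPct = "numeric", minQueryCov = "numeric",
        maxEvalue = "numeric", aniFragmentLen = "integer",
        nPermutations = "integer", hashSeed = "integer", rngSeed = "integer"
    )
)

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@kmerSize < 1L || object@kmerSize > 32L)
        msg <- c(msg, "kmerSize must be in [1, 32]")
    if (object@sketchSize < 1L)
        msg <- c(msg, "sketchSize must be positive")
    if (!(object@sgbThreshold > 0 && object@sgbThreshold < object@genusThreshold &&
          object@genusThreshold < object@familyThreshold &&
          object@familyThreshold < 1))
        msg <- c(msg, "need 0 < sgbThreshold < genusThreshold < familyThreshold < 1")
    if (object@psThreshold <= 0 || object@psThreshold > 1)
        msg <- c(msg, "psThreshold must be in (0, 1]")
    if (object@minQueryCov <= 0 || object@minQueryCov > 1)
        msg <- c(msg, "minQueryCov must be in (0, 1]")
    if (object@minIdentityPct < 0 || object@minIdentityPct > 100)
        msg <- c(msg, "minIdentityPct must be in [0, 100]")
    if (object@maxEvalue < 0) msg <- c(msg, "maxEvalue must be >= 0")
    if (object@aniFragmentLen < 15L)
        msg <- c(msg, "aniFragmentLen must be >= 15 (the ANI seed length)")
    if (object@nPermutations < 1L)
        msg <- c(msg, "nPermutations must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param kmerSize,sketchSize MinHash sketch parameters (defaults 21 and
#'   10000, the usual Mash settings).
#' @param sgbThreshold,genusThreshold,familyThreshold rank-bin distance cuts
#'   (defaults 0.05, 0.15, 0.25).
#' @param psThreshold prediction-strength support level (default 0.8).
#' @param minIdentityPct,minQueryCov,maxEvalue gene-screen hit filters
#'   (defaults 95, 0.5, 1e-5).
#' @param aniFragmentLen ANI fragment length in bases (default 1000).
#' @param nPermutations PERMANOVA permutations (default 999).
#' @param hashSeed sketch hash seed (default 42).
#' @param rngSeed default RNG seed for stochastic steps (default 1).
#' @return A validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(kmerSize = 21L, sketchSize = 10000L,
                           sgbThreshold = 0.05, genusThreshold = 0.15,
                           familyThreshold = 0.25, psThreshold = 0.8,
                           minIdentityPct = 95, minQueryCov = 0.5,
                           maxEvalue = 1e-5, aniFragmentLen = 1000L,
                           nPermutations = 999L, hashSeed = 42L,
                           rngSeed = 1L) {
    new("PipelineConfig",
        kmerSize = as.integer(kmerSize), sketchSize = as.integer(sketchSize),
        sgbThreshold = sgbThreshold, genusThreshold = genusThreshold,
        familyThreshold = familyThreshold, psThreshold = psThreshold,
        minIdentityPct = minIdentityPct, minQueryCov = minQueryCov,
        maxEvalue = maxEvalue, aniFragmentLen = as.integer(aniFragmentLen),
        nPermutations = as.integer(nPermutations),
        hashSeed = as.integer(hashSeed), rngSeed = as.integer(rngSeed))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  sketch: k =", object@kmerSize, ", s =", object@sketchSize,
        ", hashSeed =", object@hashSeed, "\n")
    cat("  rank bins: species <", object@sgbThreshold,
        "| genus <", object@genusThreshold,
        "| family <", object@familyThreshold, "| phylum >=",
        object@familyThreshold, "\n")
    cat("  subspecies: psThreshold =", object@psThreshold,
        ", aniFragmentLen =", object@aniFragmentLen, "\n")
    cat("  gene screen: identity >", object@minIdentityPct,
        "% , coverage >=", object@minQueryCov,
        ", evalue <=", object@maxEvalue, "\n")
    cat("  stats: nPermutations =", object@nPermutations,
        ", rngSeed =", object@rngSeed, "\n")
})
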