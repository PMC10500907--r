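---
title: "Strain resolution in gut metagenome collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain resolution in gut metagenome collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgbstrain)
```

# Overview

`sgbstrain` implements the analysis chain used to resolve a collection of
metagenome-assembled genomes (MAGs) — such as those binned from insect gut
shotgun metagenomes — down to species and strain level, and to screen the
accompanying gene catalog for functions of interest:

1. **Genome distances.** Bottom-s MinHash sketches of canonical k-mers give
   Mash distances between all genome pairs.
2. **Species-level genome bins (SGBs).** Average-linkage clustering of the
   distance matrix, cut at 5% distance, dereplicates MAGs into bins that
   behave as species. Each bin is classified against a reference collection
   as *known* (a reference within 5%) or *unknown*, with unknown bins placed
   at genus, family or phylum rank by their nearest-reference distance.
3. **Subspecies.** Within one SGB, fragment-based average nucleotide
   identity (ANI) distances are clustered by partitioning around medoids
   (PAM); the number of clusters is selected by the prediction-strength
   criterion (support ≥ 0.8) and visualised by classical MDS.
4. **Functional screening.** Blast-style homology hits of predicted genes
   against a curated degradation-gene catalog are filtered (e-value ≤ 1e-5,
   identity > 95%, coverage ≥ 50% of the query) and quantified as RPKM,
   then collapsed to enzyme families.
5. **Community statistics.** Binary Jaccard distances between samples,
   PERMANOVA for group effects, alpha-diversity indices and pairwise
   Wilcoxon tests.

Every stochastic input the pipeline consumes can be generated with planted
ground truth by the `simulate*()` family, which is what the test suite and
the acceptance script use throughout.

# Genome distances

A sketch keeps the $s$ smallest values of a 64-bit hash over the genome's
canonical k-mers (the lexicographically smaller of each k-mer and its
reverse complement). For two sketches $S(A)$ and $S(B)$ the Jaccard index
$j$ of the underlying k-mer sets is estimated with the union-bottom
estimator
$$\hat{j} = \frac{|X \cap S(A) \cap S(B)|}{|X|},\qquad
X = \text{bottom-}s\big(S(A) \cup S(B)\big),$$
which is unbiased for bottom sketches (the naive intersection-over-union of
the two sketches is not). The Mash distance
$$d = -\frac{1}{k}\,\ln\frac{2\hat{j}}{1+\hat{j}}$$
converts $\hat{j}$ into an estimate of per-site divergence under a Poisson
model; $d$ is 0 at $\hat{j}=1$ and saturates at 1 when $\hat{j}=0$.

Defaults are $k = 21$ and $s = 10{,}000$, the standard Mash settings; both
members of a compared pair must share $k$, $s$ and the hash seed. For
genomes with fewer than $s$ distinct canonical k-mers the sketch is the
whole set and $\hat{j}$ equals the exact k-mer Jaccard index — the test
suite exploits this to check the estimator against brute-force set
enumeration.

Two implementation constraints are worth knowing. k-mers are packed two
bits per base, so $k \le 32$; windows containing an ambiguous base (N) are
skipped. And because R doubles carry 53-bit integer precision, the stored
hash values are the top 53 bits of the mixed 64-bit hash — an
order-preserving truncation whose collision probability is negligible at
genome scale (about $10^{-4}$ per pair of 1 Mb genomes).

# Species-level genome bins

Bins are built by average-linkage agglomerative clustering cut at the 5%
distance threshold. The threshold cut is interpreted as "clusters whose
merge height is at most the threshold"; with average linkage, a chain
A–B = 0.04, B–C = 0.04, A–C = 0.08 merges {A, B} first and then places C at
height mean(0.04, 0.08) = 0.06, so the 5% cut yields {A, B} | {C}. Average
linkage was chosen over single linkage (which would chain all three) for
robustness to exactly this effect; the linkage is an explicit argument so
the choice is visible and reversible.

Classification against a reference collection is by *nearest neighbour*:
each query genome is compared with every reference sketch, and only the
smallest distance matters. Queries are never co-clustered with the
references, so bin labels do not depend on reference-set size. The rank
bins are half-open intervals — species $[0, 0.05)$, genus $[0.05, 0.15)$,
family $[0.15, 0.25)$, phylum $[0.25, 1]$ — making boundary behaviour
exact and testable; a distance of exactly 0.05 is genus, not species.
Distance ties resolve to the lexicographically first reference id.

# Subspecies detection

## Fragment ANI

The query genome is cut into non-overlapping fragments (default 1000 bp).
Each fragment is located in the target by exact-match 15-mer seeds: every
distinct candidate placement implied by a seed hit is scored by ungapped
identity over the full fragment, and the best placement wins. Fragments
reaching an identity of at least 0.75 are retained; ANI is the mean
identity of retained fragments. The estimate is directional — the query is
the fragmented side — so the pipeline computes both directions and averages
them before clustering (`aniDistanceMatrix()`), giving a symmetric matrix
of $1 - \mathrm{ANI}$ values. A pair with no retained fragment in either
direction is unalignable at this resolution and is set to the saturation
distance $1 - 0.75 = 0.25$ with a warning.

Fragments are placed on the forward strand only. The synthetic generators
produce co-oriented genomes, for which this is exact; real MAGs with
inverted segments would need strand-aware placement, a known limitation.

## PAM and prediction strength

PAM (BUILD followed by SWAP to a local optimum) clusters the ANI distance
matrix for a candidate number of clusters $k$; the implementation delegates
to the standard `cluster::pam()` engine, with the degenerate $k = n$ case
(every point a medoid, zero cost) handled directly. Note that SWAP is a
local search: on small adversarial instances its cost can sit slightly
above the exhaustive medoid-search minimum, which is the expected behaviour
of the algorithm, not a defect — on well-separated data the two coincide,
and the test suite checks exactly that.

Prediction strength asks whether a $k$-clustering is *reproducible under
resampling*: for each random 50/50 split, both halves are PAM-clustered
with $k$ clusters; test points are classified to their nearest training
medoid; each test cluster is scored by the proportion of its point pairs
that the training classifier co-assigns; the split's score is the minimum
over test clusters (singletons score 1), and the statistic is the mean over
50 splits. $k = 1$ is defined as 1. A value of at least 0.8 is taken as
support for $k$ real clusters, and the selected subspecies number is the
*largest* supported $k$ — the conventional reading of the criterion.
Candidate $k$ runs from 1 to $\min(8, \lfloor n/2 \rfloor - 1)$: beyond
that, clusters of the half-samples degenerate into singletons and the
statistic loses meaning (requesting such a $k$ is an error).

## When the criterion degenerates

One behaviour deserves explicit documentation because the synthetic data
expose it cleanly. If every genome of a subspecies is generated
independently from a common ancestor (a *star* genealogy, which is exactly
what substitution-only simulation produces) and the ANI estimator is
essentially noise-free — at 0.5% divergence every 1000-bp fragment aligns
full-length, so the estimate equals the realised mismatch fraction — then
the pairwise distances are almost perfectly *additive*:
$d(i,j) \approx a_i + a_j$, where $a_i$ is genome $i$'s realised branch
length. Under an additive metric the nearest-training-medoid classifier is
constant within a blob ($\arg\min_m (a_t + a_m)$ does not depend on $t$),
every co-assignment proportion is 1, and prediction strength is ~1 for
*every* candidate $k$, not only the planted one. The largest-supported-$k$
rule then runs to its upper bound.

In practice the criterion works because real ANI estimates carry
measurement noise comparable to the spread of within-subspecies branch
lengths, which breaks additivity; with independent within-cluster noise the
statistic shows its textbook collapse past the true $k$ (verified in the
test suite: on planted two-cluster matrices the mean prediction strength
drops from ~1 at $k=2$ to well below 0.8 for $k > 2$, and the planted
cluster number is recovered across $k_{\mathrm{true}} \in \{1,2,3\}$). The
practical reading: the 0.8 criterion is trustworthy for *whether* a split
into $k = 2$ subspecies is supported, but on near-noise-free additive
distance matrices the chosen $k$ should be treated as a lower-bound
diagnostic and inspected with the MDS plot. Passing tests on synthetic
star-planted genomes therefore validate the distance scales and the
$k = 2$ support level, not automatic model selection on real collections.

## Classical MDS

Ordination uses the classical (Torgerson) solution: eigendecomposition of
the double-centred squared-distance matrix, axes ordered by decreasing
eigenvalue, negative eigenvalues dropped. For Euclidean inputs the
embedding reproduces the configuration exactly (to 1e-9 in the tests). A
deterministic sign convention — the first nonzero loading of each axis is
made positive — keeps coordinates reproducible across platforms.
Coincident points embed at the origin.

# Functional gene screening

The hit filter follows the screening thresholds verbatim and makes the
boundary semantics explicit: e-value *at most* 1e-5 (a hit exactly at the
cutoff passes), identity *strictly greater* than 95% (exactly 95.0 fails),
alignment length *at least* 50% of the query length (exactly half passes).
When several hits of one query survive, the best is kept by bitscore, then
lower e-value, then lexicographic subject id; the multi-hit policy is a
package decision, stated here because tabular outputs do not dictate one.

RPKM is computed as
$$\mathrm{RPKM}_a = \frac{c_a \cdot 10^9}{L_a \cdot N}$$
with $c_a$ reads mapped to gene $a$, $L_a$ its length in bases and $N$ the
sample's total mapped reads. The $10^9$ factor is the kilobase-times-
million scaling the unit's name implies; informal renderings of the formula
sometimes omit it, which changes absolute values but no between-group
comparison (RPKM is invariant to jointly scaling all counts and $N$, which
is tested exactly). Family-level abundances are plain sums of member-gene
RPKM, so family totals conserve gene totals per sample.

# Community statistics

* **Jaccard distances** are computed on presence/absence (`value > 0`), per
  the index's definition; two samples with no present taxa are at distance
  0 by convention.
* **PERMANOVA** uses the distance-based pseudo-F (Anderson's formulation,
  via `vegan::adonis2`) with $p = (1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$,
  999 permutations by default, seeded for exact replay. A subtlety worth
  noting: with perfectly separated groups the attainable minimum is not
  $1/(n_\pi+1)$, because a random label permutation reproduces the group
  partition with probability $2/\binom{n}{n/2}$ and such permutations tie
  the observed F; for two groups of five that is ~0.8% of permutations.
* **Alpha diversity** reports observed richness, Shannon entropy (natural
  log), Gini–Simpson, and Pielou evenness $H/\ln(\text{richness})$, the
  latter undefined (NA) below richness 2.
* **Pairwise Wilcoxon** tests are *unpaired* two-sided rank-sum tests —
  the compared groups are independent sample pools, so the paired reading
  of "Wilcoxon" does not apply. Exact null distributions are used when
  sample sizes permit and there are no ties. Raw p-values carry the
  significance decision (the convention mirrored here), with
  Benjamini–Hochberg adjusted values reported alongside.

# Synthetic data: what it emulates and what it does not

The generators produce, with planted truth and bit-reproducibility per
seed:

* `randomGenome()` / `evolveGenome()` — i.i.d. base composition at a target
  GC and substitution-only evolution at a per-site rate. No indels, no
  rearrangements, no rate heterogeneity: this keeps the Mash and ANI
  expectations analytic (observed divergence is binomial around the rate).
* `simulateCommunity()` — a star phylogeny per species: species ancestors
  at half the target between-species divergence from a root, optional
  subspecies ancestors, leaves at half the target within-group divergence,
  so *pairwise* divergences match the stated targets up to back-mutations.
* `simulateReads()` — uniform starts, random strand, per-base errors.
* `simulateGeneCounts()` — negative-binomial counts (dispersion `size = 5`,
  typical metagenomic over-dispersion) around baseline × group multiplier,
  uniform gene lengths in 600–1500 bp, plus a constant 1e6 background of
  reads mapped elsewhere so RPKM denominators are realistic.
* `simulateComposition()` — a baseline presence profile, a planted fraction
  of taxa flipped in the non-baseline groups (turnover), 5% within-group
  presence noise, lognormal abundances for present taxa.

Real gut metagenomes additionally feature uneven coverage, chimeric and
incomplete bins, indels and rearrangements, strain mixtures within samples
and compositional (relative-abundance) constraints. Tests passing on the
synthetic data therefore demonstrate correctness of the estimators and
decision rules under their stated models — not robustness to assembly and
binning artefacts.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one CPU while staying in the
regimes the thresholds act on: 1 Mb genomes for the species-boundary check
(sketches at full $s = 10{,}000$ capacity), 500 kb × 12 genomes for the
subspecies criterion, 20 kb genomes for the 5-species dereplication checks
(under-capacity sketches, where the Jaccard estimate is exact), and
12-vs-12 samples × 100 taxa for the PERMANOVA power setting.

Other fixed choices: ANI seed length 15 with at most 64 candidate
placements scored per fragment; asymmetry and zero-diagonal tolerance 1e-9
on distance-matrix validation; MDS eigenvalue floor 1e-12; ties broken
everywhere by lowest index / lexicographic id; all writers emit
tab-separated, '.'-decimal, UNIX-newline text at `%.17g` precision so
matrices round-trip bit-for-bit.
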