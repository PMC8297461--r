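---
title: "Methods: combining DMS studies, the mutational landscape and amino acid subtypes"
author: "dmslandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining DMS studies, the mutational landscape and amino acid subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter and their defaults, the numerical
choices at the edges, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the design was genuinely
open.

# Standardising studies

## The enrichment-ratio scale

Every study is brought onto the log2 enrichment-ratio (ER) scale: 0 for a
variant behaving like wild type, negative deleterious, positive
advantageous.  `transformScores()` supports four monotone transforms —
`identity` (scores already log2 ERs), `log2_ratio` (positive ratios
relative to wild type; non-positive ratios are an error naming the
offending record), `negate` (for deleteriousness scores) and `affine(a,
b)` for linear rescalings.  The transform is part of a study's
configuration (`studyConfig()` / YAML), because the right choice depends
on how the original authors defined their score — it cannot be inferred
from the numbers.

## Replicates, conditions, multi-mutants

`averageReplicates()` takes the arithmetic mean over replicates and over
all conditions whose policy is `average`; conditions marked `drop` are
excluded, and if any condition is marked `prefer` only preferred
conditions are kept.  The policy expresses the judgement that some
selection conditions probe broader aspects of protein function than
others; the package only executes that judgement, it does not make it.

Some studies assay sequences carrying several substitutions without
measuring each single substitution.  `collapseMultimutants()` keeps
directly measured single-substitution scores verbatim and scores an
unmeasured substitution as the mean over all sequences containing it with
at most `cap` substitutions (default 3, per-study configurable).  The
implicit assumption is approximate additivity of effects on the log scale;
the cap limits how much compound epistasis can contaminate the average.
Substitutions seen only above the cap are absent from the output rather
than guessed.

## Normalisation against the deleterious tail

`normalizeStudy()` divides every score by the *magnitude* of the median of
the study's `ceiling(0.1 n)` smallest nonsynonymous scores.  The rationale:
fully deleterious variants (nonsense mutations and equivalents) represent
complete loss of function, a state that is biologically comparable across
studies, so pinning the deleterious tail at −1 makes scores comparable.
Three deliberate details:

* **Magnitude, not value.**  The bottom-decile median is negative in any
  informative study; dividing by it directly would flip every sign and
  make deleterious scores positive.  Dividing by its absolute value
  preserves signs, and the bottom-decile median of the output is exactly
  −1.
* **Nonsynonymous pool.**  Synonymous scores cluster at 0 and can never
  reach the deleterious tail; they are excluded from the pool (but are
  rescaled with everything else).  The threshold targets nonsense-like
  scores, so the pool is all missense + nonsense scores.
* **Degenerate studies.**  A bottom-decile median of 0 means the study has
  no deleterious tail and cannot be anchored; this is an error, not a
  silent pass-through.  Fewer than 10 nonsynonymous scores is likewise an
  error — a decile of fewer than one value is meaningless.

Normalisation is invariant to positive rescaling of its input by
construction, which is exactly why multiplicative study-to-study scale
differences do not propagate.

One consequence worth understanding: because the anchor is the *tail*
median, the typical loss-of-function score lands slightly above −1 in
noisy data (the tail selects the extreme draws).  This is inherent to the
method, not a bug; subtype clustering is robust to it because cosine
distance ignores overall magnitude.

## Filtering and imputation

Positions with fewer than 15 of the 20 nonsynonymous substitutions
measured are dropped (`filterPositions()`; the count is over 19 missense +
nonsense — synonymous measurements do not count).  The order matters and
is fixed: normalisation happens per study *before* filtering, so sparse
positions still inform the study's deleterious tail before being removed;
the test suite pins this order on a fixture where reversing it changes the
output.

`imputeMissing()` fills each remaining missense or nonsense gap with the
median normalised score of the same substitution type pooled across all
studies, and missing synonymous entries with 0 (measured synonymous scores
overwhelmingly sit at 0).  Imputation medians are computed once over the
full combined dataset; adding a study changes the pool, so medians are
recomputed rather than cached.  A type never measured anywhere cannot be
imputed and raises an error listing the type.  The `imputed` assay of the
resulting `MutationalLandscape` records exactly which entries were filled,
so any downstream analysis can condition on measurement status.

Positions covered by several studies stay as separate profiles keyed by
study: independent measurements of the same site are replication, not
redundancy, and merging them would hide inter-study disagreement.
Wild-type disagreements between studies of one gene produce a warning and
keep both declarations.

# The landscape

## PCA

`fitPCA()` is a full-rank 20-dimensional PCA (centred, unscaled).  Column
signs are fixed so each loading's largest-magnitude element is positive —
PCA signs are arbitrary, and a convention keeps serialised models and
downstream centroids stable across platforms.  On landscapes dominated by
overall-magnitude variation, PC1's scores correlate almost perfectly with
mean ER (the acceptance run computes r² ≈ 0.99+ on the default synthetic
landscape), which motivates excluding PC1 from subtype clustering.

## UMAP

`fitUMAP()` embeds the raw 20-dimensional profiles (not PC scores — the
embedding and the PCA are parallel views of the same data) with Euclidean
metric, `n_neighbors = 15`, `min_dist = 0.1`, via `uwot`.  The run is
single-threaded with a fixed seed, making embeddings bit-reproducible, and
the returned transformer supports out-of-sample projection.  UMAP
coordinates are for visualisation and neighbourhood structure only;
nothing quantitative downstream depends on them.

## Summaries

`meanER()` (mean of the 20 entries), `substitutionTypeMeans()` (20×20 mean
ER per wild-type→target pair; the diagonal is the synonymous mean),
`meanERAway()` (mean of the 19 missense entries per wild-type amino acid)
and `aggregatePositionAnnotations()` (per-position means of user-supplied
per-substitution annotation terms, e.g. stability-change components)
implement the standard landscape descriptors.  `blosumComparison()`
correlates the missense substitution-type means with BLOSUM62 (via
`Biostrings`) as an evolutionary sanity check; it is a convenience
statistic, not a gate.

# Amino acid subtypes

## The three steps

Per wild-type amino acid X:

1. **Permissive split** (`splitPermissive()`): positions with |ER| < 0.4
   for all 20 entries become `XP`.  Cosine distance measures angle; a
   near-zero profile's direction is noise, and an exactly-zero vector has
   no direction at all.  The split both removes that hazard structurally
   and captures a biologically meaningful class (positions tolerating
   everything).
2. **Clustering**: average-linkage hierarchical clustering with cosine
   distance on PC2–PC20 scores.  The PCA basis is fit on the *whole*
   landscape, permissive positions included; only the clustering excludes
   them.
3. **Hybrid dynamic tree cut** (`dynamicHybridCut()`), then labelling:
   clusters renumbered `X1, X2, …` by decreasing size, unassigned
   positions `XO`.

## The tree cut

A fixed-height dendrogram cut cannot adapt to clusters of different
densities.  The package's hybrid dynamic cut works in two stages:

*Stage 1 — branch detection.*  Merges are processed bottom-up.  Each
branch accumulates members with the height at which each one attached.
When two branches meet at height *h*, a branch qualifies as a cluster if
it (i) has at least `minClusterSize` members, (ii) has a tight core — the
mean attachment height of its core members (core size
`minClusterSize/2 + 1 + sqrt(n − minClusterSize/2 − 1)`) is at most
`maxCoreScatter`, and (iii) stands clear of the merge: `h` minus the core
scatter is at least `minGap`.  Judging the gap from the branch core rather
than the branch top is deliberate: stragglers that chain onto a tight
cluster late (noise points between clusters) would otherwise erase the
gap and cause systematic under-splitting.  If both branches qualify they
are finalised as separate clusters; otherwise they merge and climb on.
Merges above the cut height (99% of the maximum merge height) close
branches independently.  `maxCoreScatter` and `minGap` are expressed as
fractions of the height range between a reference height (the 5th
percentile merge) and the cut height, with the two published sensitivity
presets: `deepSplit = 0` → (0.64, 0.27), `deepSplit = 1` → (0.73, 0.2025).

*Stage 2 — straggler assignment.*  Each unlabelled point is attached to
the cluster with the smallest mean distance to its members, provided that
distance is within the cluster's assignment radius (the largest mean
intra-cluster distance of any member); points beyond every radius stay
outliers.

Degenerate inputs are handled explicitly: a dendrogram whose first merge
already exceeds the cut height (all points equally close, including
all-identical points) is treated as a single branch, yielding one cluster
when it meets the minimum size and all outliers otherwise; asymmetric or
mismatched distance matrices are errors.

`deepSplit` defaults to 0 for every amino acid and is configurable per
amino acid (`clusteringParams(deepSplit = c(C = 1))`): landscapes differ
in how finely their dendrograms should be split, and the right value is a
judgement about profile consistency within resulting subtypes.
`minClusterSize` defaults to 20 — below that, a recurring profile shape is
hard to distinguish from coincidence at current landscape sizes.

## Labels and characterisation

Numbering is by decreasing size; ties are broken by smaller mean
intra-cluster cosine distance, then by lowest member index, so the
labelling is deterministic and invariant to input order.
`subtypeProfiles()` reports size, frequency (relative to all positions of
that amino acid) and the entrywise-mean profile; `correlateSubtypes()`
groups subtypes across amino acids by average-linkage clustering on
1 − Pearson correlation of their mean profiles, which is how recurring
cross-amino-acid patterns (e.g. "rejects proline") surface.
`mostSelectiveSubtype()` returns, per amino acid, the numbered subtype
with the lowest mean profile mean.  "Most selective" admits two readings —
lowest mean ER (most intolerant, the default here) or highest mean ER; the
`direction` flag exposes both rather than guessing which a given analysis
wants.

`saturationAnalysis()` reruns the whole subtype pipeline (PCA refit
included) on nested random subsets (default: from 1,000 positions in steps
of 200, 100 shuffles) and counts numbered subtypes, to ask whether the
catalogue is saturating.  Everything is driven by one seed and is exactly
reproducible.

# Projection of new studies

`buildReferenceBundle()` freezes the PCA model, the UMAP transformer with
its parameters and seed, per-subtype centroids in the clustering PC range,
an outlier radius per subtype, the pooled imputation medians and the
permissive threshold.  Design decisions:

* **Nearest centroid with a radius.**  A new position is `XP` if all its
  entries are below the permissive threshold; otherwise it goes to the
  nearest same-amino-acid centroid by cosine distance, or `XO` if that
  distance exceeds the subtype's radius.  This mirrors the clustering
  geometry and is simple enough to reason about and test.
* **Radius = 95th percentile** of member-to-centroid distance, computed as
  the inverted-ECDF quantile (type 1): the radius is then an actual member
  distance and provably covers at least 95% of members.  Interpolating
  quantile definitions can leave more than 5% of a small cluster outside
  its own "95%" radius, quietly degrading the reference's
  self-consistency.
* **Reference medians for gaps.**  A new study's missing entries are
  imputed from the bundle's stored medians, not from the new study itself:
  the reference defines the coordinate system, and a handful of new
  positions cannot estimate stable type medians anyway.
* **Serialisation.**  The bundle is a JSON file plus a TSV sidecar of the
  reference profiles.  Doubles are written with 17 significant digits so
  they survive the round trip bit-exactly — boundary decisions (a distance
  exactly at a radius) would otherwise flip after a save/load cycle.  The
  UMAP transformer itself is not text-serialisable; `readReferenceBundle()`
  rebuilds it deterministically by refitting on the stored profiles with
  the stored seed.

Projected PC scores of reference positions reproduce their stored scores
to numerical precision; the UMAP transform of a training point is *not*
guaranteed to reproduce its training coordinates exactly (that is inherent
to the method), which is why subtype assignment runs through PCA space,
not the embedding.

# The synthetic-data generator

`generateLandscape()` exists so that every claim the package makes can be
tested against known ground truth.  It emulates, per study: per-position
20-entry profiles drawn from amino-acid-specific archetypes, a
multiplicative study scale (removed by normalisation), replicate-level
Gaussian noise, missing entries, strongly negative nonsense scores,
measured synonymous scores near 0, and optionally multi-mutant sequences
with additive effects plus Gaussian epistasis
(`generateMultimutants()`).

Default study conditions: 4 studies × 500 positions; study scales
(1, 2, 5, 0.5); 3 replicates; per-entry effect noise SD 0.08 with
replicate noise SD 0.12 (replicate-averaged entry noise ≈ 0.106 — the
regime of high-quality scans); missingness 2% (matching the ~98% measured
fraction typical of well-covered combined landscapes) applied completely
at random.

The archetype library is binary 0/−1 templates: permissive, fully
intolerant, not-proline, and requires-{hydrophobic, small, aromatic,
negative, positive}.  Each wild type draws from two selective chemical
classes with *near-disjoint tolerated sets*, plus not-proline and
permissive (weights 0.3/0.3/0.2/0.2).  The disjointness is deliberate:
after the mean-ER direction is removed, two classes that share most of
their deleterious pattern (e.g. "fully intolerant" versus "requires
negative" at an aspartate, which differ in a single coordinate) are not
distinct position types in any meaningful sense — their profile directions
are nearly parallel and no clustering method should be expected to
separate them at realistic noise.  For the same reason the fully
intolerant class is planted only at hydrophobic wild types, where the
broad hydrophobic-requiring class leaves it a distinct direction.  Proline
swaps the (degenerate at wild-type P) not-proline class for a second
chemical class.

What the generator does **not** emulate: sequence correlations between
neighbouring positions, study-specific substitution biases or codon-level
artefacts, missingness that depends on the score (real dropouts are not
MCAR), non-Gaussian score noise, condition-dependent selection differences
within a study, and disagreement between studies about a position's true
profile.  Passing the planted-recovery tests therefore shows the pipeline
is correct and well-calibrated *for its own model of the data*; it does
not show that real landscapes decompose this cleanly, and on real data the
per-amino-acid `deepSplit` choice in particular requires judgement.

# Verification strategy and problem sizes

The test suite checks each operation against hand-computed values on tiny
fixtures, property-style invariants (normalisation scale-invariance,
partition laws, order-invariance of clustering), and planted-truth
recovery end to end.  Cluster recovery is scored two ways: label agreement
with the planted partition on 25 random well-separated cosine-geometry
instances (n ≤ 200, ≥ 95% of points), and adjusted Rand index ≥ 0.8
between planted and recovered subtypes on the default 2,000-position
landscape, where both permissive-planted positions and
permissive/outlier-labelled positions are excluded from the comparison so
that it measures exactly the recovery of selective classes.  The
acceptance script reruns the full pipeline at the default scale
(2,000 positions), the saturation analysis with 3 shuffles at a 500-step,
and a 500-draw projection check; these sizes were chosen as the smallest
at which the landscape-level statistics are stable.

# Known limitations

* The Dynamic Hybrid cut implemented here follows the published two-stage
  algorithm and its `deepSplit` parameter presets, but it is this
  package's own implementation; branch-by-branch agreement with other
  implementations on ambiguous (non-separated) instances is not
  guaranteed.
* Cosine geometry makes all magnitude information invisible to the
  subtype step; two positions with the same shape at different depths of
  deleteriousness are the same subtype.  That is a feature for role
  classification and a limitation for anything dose-dependent.
* The permissive threshold (0.4) is inherited as a fixed convention; on
  landscapes with different noise levels the right threshold may differ,
  and positions imputed across the threshold are classified by their
  imputed profile.
* Projection assumes the new study normalises onto the same scale as the
  reference; a study whose deleterious tail is unusual (e.g. no nonsense
  variants and few fully deleterious missense variants) will be anchored
  differently, and its projected coordinates inherit that shift.
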