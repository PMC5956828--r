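---
title: "Statistically driven slide classification and anomaly detection from tile embeddings"
author: "embedclass authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistically driven slide classification and anomaly detection from tile embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(embedclass)
```

## The problem

Deep networks trained to classify histology image tiles output softmax
probability vectors, and most whole-slide classification workflows average
those vectors and threshold the top score. That works well for closed,
binary tasks, but degrades in practice for two reasons. First, with many
output classes the meaning of a probability cutoff becomes
context-dependent, and choosing it requires post-hoc ROC analysis on a
labelled validation cohort. Second — and more fundamentally — the softmax is
a closed-set readout: a tumour type the network has never seen still
receives a confident score for *some* trained class. In diagnostic
neuropathology, where the five common tumour families (gliomas,
meningiomas, schwannomas, metastases, lymphomas) coexist with more than a
hundred rare entities, the inputs a classifier should *refuse* to classify
are exactly the ones it scores most misleadingly.

`embedclass` implements an alternative, visual and statistically driven
readout that works from the network's *feature space* rather than its
softmax. It renders graded verdicts the way a pathologist does: a single
**diagnosis** when the evidence is unambiguous, a **differential
diagnosis** when several classes are statistically indistinguishable, and
**undefined** when the slide does not resemble anything the model was
trained on.

## The procedure

1. **Tiling and gating.** Slides are cut into fixed 1024 px tiles
   (0.504 µm/pixel). A lesion-vs-rest model scores each tile; only tiles
   with lesional probability strictly above 0.85 are considered
   diagnostic. Slides with fewer than 15 such tiles are not classified at
   all — they are flagged, and up to five of the highest-scoring tiles are
   handed to the pathologist for manual review. Up to 100 gated tiles per
   slide are sampled uniformly at random.

2. **Reference map.** 350–600 training tiles per class (at full scale) are
   embedded on a plane with t-SNE from their deep feature vectors. The map
   is refined once: every point whose 300 nearest map neighbours are
   mostly (< 50%) of other classes is removed as a suspected mislabel or
   mixed-content tile.

3. **Joint re-embedding.** For each test slide, the embedding is re-run
   from scratch on the union of reference tiles and the slide's sampled
   tiles. The global cluster structure is stable under the addition of
   ≤ 100 query points; query tiles simply land where they belong.

4. **Discretization.** Each query tile looks at its 25 nearest *reference*
   points on the plane (query tiles never vote). If at least 85% of them
   carry one class label — i.e. at least 22 of 25 — the tile is discretized
   to that class; otherwise it is an **outlier**, a tile in unoccupied or
   contested space.

5. **Verdict.** The per-slide counts of discretized tiles form a
   contingency table that is tested against a random, equally partitioned
   distribution with a plain chi-square goodness-of-fit statistic
   (Σ(Oᵢ−E)²/E, E = N/k, df = k−1; no continuity correction, no
   minimum-count guard — the tables hold 15–100 tiles by construction).
   If the first test is significant at α = 0.01 *and* the outlier
   category is modal, the slide is **undefined**: it contains too many
   anomalous features to classify. Otherwise outliers are set aside and
   the smallest class is iteratively removed until the remaining
   distribution is no longer significantly non-uniform (p ≥ α): one
   survivor is the **diagnosis**, several survivors form the
   **differential**. Because α is fixed a priori, no ROC-derived cutoff
   enters the decision.

6. **Composites.** The package also computes the classical baseline (mean
   softmax over gated tiles, top class wins), a conservative **combined**
   rule (classify only when map verdict and probability baseline agree on
   a single class), and a **hybrid** score
   s_c = w·frac_c + (1−w)·meanprob_c blending tile fractions with mean
   probabilities (w = 0.5 by default; the blend weight is exposed because
   no canonical value exists).

7. **Evaluation.** Predictions are scored against ground truth with a
   macro-averaged one-vs-rest multiclass ROC (trapezoidal integration,
   midrank ties), accuracy/coverage sweeps over confidence cutoffs, and an
   error taxonomy: **Type A** (normal tissue called lesion), **Type B**
   (wrong lesion class among trained classes), **Type C** (untrained class
   called as a trained class). Differential/undefined/insufficient slides
   are excluded from accuracy — they are handoffs to a human, not
   predictions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tileSize` | 1024 px | tile edge length |
| `micronsPerPixel` | 0.504 µm | physical scale of a pixel |
| `lesionalThreshold` | 0.85 | lesional gate, strict `>` |
| `minLesionalTiles` | 15 | minimum gated tiles to classify (5 in the lax variant) |
| `maxTilesPerSlide` | 100 | per-slide sampling budget |
| `knnK` | 25 | neighbours examined per query tile |
| `knnPurity` | 0.85 | modal-class fraction required (`>=`) |
| `alpha` | 0.01 | chi-square significance level |
| `perplexity` | 30 | t-SNE neighbourhood size |
| `nCheckNeighbors` | 300 | refinement neighbour count |
| `ownClassMin` | 0.5 | refinement own-class threshold |
| `hybridWeight` | 0.5 | tile-fraction weight of the hybrid score |

Two boundary conventions deserve note. The lesional gate is *strict*
(a tile at exactly 0.85 is rejected) while the purity rule is *inclusive*
(a tile at exactly 85% purity is discretized); at k = 25 the purity
boundary cannot actually be hit (22/25 = 0.88 is the effective rule), but
the convention matters for other k. The minimum-tile rule is implemented
as "at least 15 tiles proceed" — a slide with exactly 15 gated tiles is
classified, one with 14 is flagged.

## What the synthetic generator emulates — and what it does not

Testing the workflow end to end requires labelled tile features, per-tile
probabilities and slides with known truth, including truly novel classes.
The `fixtures` generator provides them without any trained network:

* **Class clusters.** Each trained class is an isotropic Gaussian in
  feature space. Class means are seeded random directions scaled to a
  common radius, accepted only when every pairwise distance reaches
  `classSeparation × withinClassSd` (default 10 SD). Placement failures
  (e.g. 13 classes in 2 dimensions) raise an error naming the constraint.
* **Mock CNN head.** Class probabilities are the softmax of
  −d²/temperature against the class means — monotone in cluster
  membership, like a calibrated classifier head — and the lesional
  probability is the summed mass of the five lesion classes, exactly
  mirroring the two-model (lesion gate + 13-class) design.
* **Slides.** A trained-class slide holds `nLesional` tiles from its
  truth cluster plus background tiles from non-lesional clusters — the
  background reliably fails the lesional gate, exercising the gating
  path. A novel slide's tiles come from a cluster planted **in the
  unoccupied interior** of the class-mean sphere: the closest admissible
  point to the origin along a seeded random direction, at least
  `offsetSd` (default 10 SD) from every trained mean. Probabilities are
  still computed against the trained means — the mock network knows
  nothing of the novel class — so novel tiles carry confident, wrong
  softmax scores, reproducing the closed-set failure mode the map-based
  verdict is designed to catch.

**Feature dimensionality matters, and its default (1024) is deliberate.**
The within-class squared distance between two tiles concentrates around
2D·σ² with fluctuations of order √(8D)·σ², while the cross-class excess
is fixed at `classSeparation²·σ²`. In low dimension (say D = 64) the
excess is several fluctuation SDs, the neighbour graph decouples into 13
disconnected islands, and a novel cluster's position relative to the
islands becomes an arbitrary by-product of the embedding — it can land
flush against one island and inherit pure, wrong neighbourhoods. At
D ≈ 1024, the scale of the final hidden layers of VGG-style encoders, the
excess is ~1.5 fluctuation SDs: classes remain perfectly separable by
nearest mean (that margin is D-independent) but the neighbour graph
becomes class-adjacent, the map shows touching clusters with a bounded
unoccupied interior, and interior novel clusters acquire genuinely mixed
neighbourhoods. This is the regime real CNN features occupy, and the
package's open-set behaviour should be read as conditional on it.

For the same reason the t-SNE backend is run **without PCA
pre-reduction**: projecting 1024-d features to 50 components first
discards most within-class variance, artificially re-separating the
classes and undoing the realistic neighbour structure.

The generator does **not** emulate: pixel content (no H&E texture; tile
images are out of scope), staining and scanner variation, anisotropic or
correlated CNN feature noise, class imbalance beyond the per-class count
range, spatial correlation of neighbouring tiles on a slide, or novel
classes that overlap trained ones. Passing tests therefore demonstrate
that the *statistical machinery* — gating, discretization, iterative
testing, open-set rejection — behaves as specified on data with the
assumed cluster geometry; they do not certify performance on real
histology, which depends on the quality of the upstream network.

## Numerical and design choices

* **Embedding initialisation.** Joint re-embeddings use seeded random
  initialisation. We evaluated PCA initialisation (attractive for
  run-to-run stability) and found a systematic artifact: a novel cluster's
  top-2-PC projection falls onto or near the image of its closest trained
  cluster, the optimisation never escapes it, and open-set detection
  collapses. With seeded random initialisation runs remain exactly
  reproducible — determinism comes from the seed — without the bias.
* **Seeding.** Every stochastic step (tile sampling, t-SNE) derives a
  31-bit seed from the pipeline seed and the slide identifier, so
  per-slide results are independent of processing order and repeated runs
  are byte-identical.
* **Refinement scale.** The 300-neighbour refinement check presumes
  several hundred reference tiles per class; a class of n points can never
  reach a 50% own-class fraction among ≫ 2n neighbours. At the desk scale
  used by the test suite (50 tiles per class) the check runs with
  `nCheckNeighbors = 50`. Refinement is single-pass and idempotent on its
  own output.
* **Tie-breaking.** Distance ties at the k-th neighbour resolve by
  reference point order; modal-class ties by label order; smallest-class
  elimination ties by label order; probability-top ties by column order.
  All are deterministic.
* **Degenerate tables.** A single-category chi-square is non-informative
  and returns p = 1 by convention (df = 0); a slide whose table is pure
  outliers is undefined even when the one-category test cannot be
  significant, because nothing diagnosable remains.
* **First-iteration outlier rule.** "Significant and outlier-modal" is the
  operationalisation used: the undefined verdict requires both a
  non-uniform first table and the outlier category holding a plurality
  (ties count as modal). Outliers never appear in a differential.
* **Sweep orientation.** In the outlier-cutoff sweep the confidence score
  is the fraction of tiles in *defined* space (1 − outlier fraction), so
  that raising the cutoff is uniformly stricter in both sweep modes and
  coverage is monotone non-increasing.
* **mROC construction.** Multiclass ROC is approximated by macro-averaged
  one-vs-rest AUCs with trapezoidal integration (equivalent to midrank
  Mann–Whitney); the map-based classifier's score vector is its per-class
  assigned-tile fraction with outliers excluded.

## Problem sizes

The test suite and the acceptance script run the full workflow at desk
scale, chosen to keep a complete run in minutes on one CPU while
preserving every structural property of the full-scale setting: 13
classes, 1024-d features, 50 reference tiles per class (650 map points),
50 trained-class slides of 40–100 lesional plus 20–60 background tiles,
20 novel slides of 100 tiles, and 10,000 replicates for the type-I
calibration of the first chi-square iteration. The reference-set
*default* remains 350–600 tiles per class, the full-scale operating
point.

## Known limitations

* Open-set detection quality is a property of the embedding geometry; for
  feature spaces whose untrained classes project inside trained clusters
  (e.g. low-dimensional or heavily compressed features), undefined recall
  will degrade — the generator's dimensionality discussion above is the
  relevant caveat.
* The chi-square verdict treats tiles as independent draws; spatially
  adjacent tiles of a slide are correlated in reality, which makes the
  nominal α an approximation at the slide level.
* Per-slide joint re-embedding is O(reference + budget) per slide and is
  re-run from scratch for every slide, the dominant cost of the pipeline.
* Pyramidal whole-slide formats, stain normalisation and tissue masking
  are out of scope; inputs are plain rasters or pre-computed per-tile
  feature tables.
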