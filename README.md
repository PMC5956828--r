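# embedclass

Transparent, statistically driven classification and anomaly detection for
whole-slide histology images, working from deep feature embeddings of image
tiles rather than softmax scores alone.

## Who this is for

Computational pathology groups building slide-level decision support on top
of a tile classifier (CNN or otherwise). The usual readout — average the
softmax over tiles, report the top class — needs post-hoc ROC-tuned cutoffs
and, worse, cannot *refuse* to classify: a tumour type the network never saw
still gets a confident score for some trained class. `embedclass`
implements a complementary open-set readout that renders graded verdicts
the way a pathologist does: **diagnosis**, **differential diagnosis**, or
**undefined**.

## The method

Per slide, with all thresholds fixed a priori:

1. Keep tiles whose lesional probability is strictly above 0.85; require at
   least 15 such tiles (otherwise flag the slide and hand up to 5 tiles to
   the pathologist); sample up to 100.
2. Re-embed the labelled reference tiles (350–600 per class at full scale)
   together with the slide's tiles on a 2-D t-SNE map.
3. Discretize each tile by its 25 nearest reference points: if ≥ 85% carry
   one class label (≥ 22 of 25), the tile takes that class; otherwise it is
   an **outlier** in unoccupied map space.
4. Test the tile counts against a uniform partition with the chi-square
   goodness-of-fit statistic

   χ² = Σᵢ (Oᵢ − E)² / E,  E = N/k,  df = k − 1.

   If the first test is significant (p < α = 0.01) *and* outliers are the
   modal category → **UNDEFINED**. Otherwise drop the outlier category and
   iteratively remove the smallest class while p < α: one survivor is the
   **DIAGNOSIS**, several survivors the **DIFFERENTIAL**.
5. Alongside, compute the classical mean-softmax baseline, a conservative
   **combined** call (only when both classifiers agree on one class) and a
   **hybrid** score s_c = w·frac_c + (1−w)·meanprob_c.

Evaluation utilities provide macro one-vs-rest mROC AUC, accuracy/coverage
sweeps, and the Type A/B/C error taxonomy (normal-as-lesion, wrong lesion
class, untrained-as-trained).

A synthetic fixture generator (Gaussian class clusters with a
squared-distance softmax head, slide mixtures, and novel interior clusters)
lets the whole workflow run and be tested without any trained network; see
the methods vignette (`vignettes/embedclass-methods.Rmd`) for what it does
and does not emulate.

## Worked example

```r
library(embedclass)

cfg <- fixtureConfig(tilesPerClassRange = c(40L, 40L), seed = 42)  # 13 classes
ref <- makeReferenceSet(cfg)
pc  <- pipelineConfig(seed = 42, nCheckNeighbors = 40L)

map <- buildReferenceMap(ref, perplexity = 30, seed = 42)
map <- refineReferenceMap(map, nCheckNeighbors = 40, ownClassMin = 0.5)
ref <- applyRefinement(ref, map)

slide  <- makeSlide(cfg, "meningioma", nLesional = 80, nBackground = 40, seed = 7)
classifySlide(slide, ref, pc)
#> SlideReport for slide slide_meningioma_s7
#>   tiles:  input=120, gated=80, sampled=80
#>   map verdict: DIAGNOSIS [meningioma]
#>   probability top class: meningioma
#>   combined: meningioma
```

The 40 background tiles fail the lesional gate (120 → 80); the 80
meningioma tiles land in the meningioma cluster, the chi-square trail
eliminates the single stray outlier call, and all three classifiers agree.

A slide from a tumour type the mock network never saw:

```r
novel <- makeNovelSlide(cfg, offsetSd = 10, nTiles = 100, seed = 8)
nrep  <- classifySlide(novel, ref, pc)
nrep
#> SlideReport for slide slide_novel_s8
#>   tiles:  input=100, gated=29, sampled=29
#>   map verdict: UNDEFINED
#>   probability top class: lymphoma
#>   combined: UNDEFINED
nrep@contingency
#>     glioma meningioma    OUTLIER
#>          2          2         25
```

The softmax baseline confidently (and wrongly) says "lymphoma" — the
closed-set failure mode — while 25 of 29 tiles fall into unoccupied map
space and the slide is correctly refused as UNDEFINED.

A thin command-line front end is installed with the package
(`exec/embedclass`): `simulate`, `build-map`, `classify`, `evaluate`
subcommands over the same functions.

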