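#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

## The thirteen tissue classes of the default model: five lesion (tumour)
## classes plus eight non-lesional tissue/artifact classes routinely found
## on neurosurgical slides.
.default_class_names <- c(
  "glioma", "meningioma", "schwannoma", "metastasis", "lymphoma",
  "hemorrhage", "surgical_material", "dura", "necrosis", "blank",
  "grey_matter", "white_matter", "cerebellum"
)

#' Label used for tiles that cannot be discretized into a trained class
#' @export
OUTLIER_LABEL <- "OUTLIER"

# ---------------------------------------------------------------------------
# FixtureConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic feature-space generator
#'
#' Describes a mock CNN feature space: one isotropic Gaussian cluster per
#' trained tissue class, with class means placed at a guaranteed minimum
#' mutual distance. The generator stands in for a trained network so that the
#' whole classification workflow can be exercised without images or weights.
#'
#' @slot nClasses number of trained classes.
#' @slot featureDim dimensionality of the mock embedding space. The default
#'   (1024) is on the scale of the final hidden layers of VGG-style encoders;
#'   see the package vignette for why the dimensionality matters for
#'   realistic neighbour structure.
#' @slot classSeparation minimum distance between any two class means, in
#'   units of \code{withinClassSd}.
#' @slot withinClassSd isotropic standard deviation of each class cluster.
#' @slot tilesPerClassRange inclusive \code{c(lower, upper)} range from which
#'   per-class reference tile counts are drawn.
#' @slot lesionClassIds indices (into \code{classNames}) of the classes
#'   treated as lesional; the remaining classes model normal tissue and
#'   artifacts.
#' @slot softmaxTemperature temperature of the squared-distance softmax used
#'   to convert feature-space geometry into mock class probabilities.
#' @slot classNames ordered class labels.
#' @slot seed integer seed; all generator output is a pure function of the
#'   configuration (including this seed).
#'
#' @seealso [fixtureConfig()], [makeReferenceSet()], [makeSlide()],
#'   [makeNovelSlide()]
#' @export
setClass("FixtureConfig", representation(
  nClasses = "integer",
  featureDim = "integer",
  classSeparation = "numeric",
  withinClassSd = "numeric",
  tilesPerClassRange = "integer",
  lesionClassIds = "integer",
  softmaxTemperature = "numeric",
  classNames = "character",
  seed = "integer"
))

setValidity("FixtureConfig", function(object) {
  msg <- character(0)
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@featureDim < 2L) msg <- c(msg, "featureDim must be >= 2")
  if (object@classSeparation <= 0) msg <- c(msg, "classSeparation must be > 0")
  if (object@withinClassSd <= 0) msg <- c(msg, "withinClassSd must be > 0")
  r <- object@tilesPerClassRange
  if (length(r) != 2L || r[1] < 1L || r[1] > r[2])
    msg <- c(msg, "tilesPerClassRange must be c(lower, upper) with 1 <= lower <= upper")
  ids <- object@lesionClassIds
  if (length(ids) == 0L || any(ids < 1L) || any(ids > object@nClasses) ||
      anyDuplicated(ids))
    msg <- c(msg, "lesionClassIds must be a non-empty subset of 1..nClasses")
  if (object@softmaxTemperature <= 0) msg <- c(msg, "softmaxTemperature must be > 0")
  if (length(object@classNames) != object@nClasses)
    msg <- c(msg, "classNames must have length nClasses")
  if (anyDuplicated(object@classNames)) msg <- c(msg, "classNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-fixture configuration
#'
#' @param nClasses number of trained classes.
#' @param featureDim embedding dimensionality.
#' @param classSeparation minimum inter-mean distance in within-class SD units.
#' @param withinClassSd within-class standard deviation.
#' @param tilesPerClassRange inclusive range of reference tiles per class.
#' @param lesionClassIds indices of lesional classes (1-based).
#' @param softmaxTemperature temperature of the mock probability softmax.
#' @param classNames class labels; defaults to the 13 neuropathology tissue
#'   classes (or generic labels when \code{nClasses} differs from 13).
#' @param seed integer seed.
#' @return A [FixtureConfig-class] object.
#' @examples
#' cfg <- fixtureConfig(nClasses = 3, featureDim = 32,
#'                      tilesPerClassRange = c(10, 10), seed = 7)
#' @export
fixtureConfig <- function(nClasses = 13L, featureDim = 1024L,
                          classSeparation = 10, withinClassSd = 1,
                          tilesPerClassRange = c(350L, 600L),
                          lesionClassIds = 1:5,
                          softmaxTemperature = 1,
                          classNames = NULL, seed = 0L) {
  nClasses <- as.integer(nClasses)
  if (is.null(classNames)) {
    classNames <- if (nClasses == 13L) .default_class_names
                  else sprintf("class%02d", seq_len(nClasses))
  }
  ## the default lesion set must leave at least one non-lesional class
  if (identical(lesionClassIds, 1:5) && nClasses <= 5L)
    lesionClassIds <- seq_len(max(1L, nClasses - 1L))
  new("FixtureConfig",
      nClasses = nClasses,
      featureDim = as.integer(featureDim),
      classSeparation = as.numeric(classSeparation),
      withinClassSd = as.numeric(withinClassSd),
      tilesPerClassRange = as.integer(tilesPerClassRange),
      lesionClassIds = as.integer(lesionClassIds),
      softmaxTemperature = as.numeric(softmaxTemperature),
      classNames = classNames,
      seed = as.integer(seed))
}

setMethod("show", "FixtureConfig", function(object) {
  cat("FixtureConfig:", object@nClasses, "classes in",
      object@featureDim, "dimensions\n")
  cat("  separation:", object@classSeparation, "x sd =",
      object@classSeparation * object@withinClassSd, "\n")
  cat("  reference tiles/class: [", object@tilesPerClassRange[1], ",",
      object@tilesPerClassRange[2], "]\n")
  cat("  lesional classes:",
      paste(object@classNames[object@lesionClassIds], collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# PipelineConfig
# ---------------------------------------------------------------------------

#' Configuration of the slide classification pipeline
#'
#' Holds every tunable threshold of the workflow. The defaults implement the
#' standard operating point: 1024-pixel tiles at 0.504 um/pixel, a strict
#' 85\% lesional-probability gate, a minimum of 15 gated tiles per slide, a
#' budget of 100 randomly sampled tiles, 25-nearest-neighbour discretization
#' at 85\% purity, and iterative chi-square testing at significance level
#' 0.01.
#'
#' @slot tileSize tile edge length in pixels.
#' @slot micronsPerPixel physical pixel size in micrometres.
#' @slot lesionalThreshold lesional-probability gate; tiles are kept only if
#'   strictly greater than this value.
#' @slot minLesionalTiles minimum number of gated tiles required to classify
#'   a slide.
#' @slot maxTilesPerSlide per-slide tile budget for the embedding step.
#' @slot knnK number of reference neighbours examined per query tile.
#' @slot knnPurity modal-class fraction required to discretize a tile.
#' @slot alpha significance level of the chi-square decision procedure.
#' @slot perplexity t-SNE perplexity for map construction and per-slide
#'   re-embedding.
#' @slot nCheckNeighbors neighbour count of the reference-map refinement
#'   check (scale it down with the per-class reference size; see vignette).
#' @slot ownClassMin own-class fraction below which a reference point is
#'   removed during refinement.
#' @slot hybridWeight weight of the tile-fraction term in the hybrid score.
#' @slot seed integer seed driving all stochastic steps.
#' @seealso [pipelineConfig()], [classifySlide()]
#' @export
setClass("PipelineConfig", representation(
  tileSize = "integer",
  micronsPerPixel = "numeric",
  lesionalThreshold = "numeric",
  minLesionalTiles = "integer",
  maxTilesPerSlide = "integer",
  knnK = "integer",
  knnPurity = "numeric",
  alpha = "numeric",
  perplexity = "numeric",
  nCheckNeighbors = "integer",
  ownClassMin = "numeric",
  hybridWeight = "numeric",
  seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  if (object@tileSize < 1L) msg <- c(msg, "tileSize must be >= 1")
  if (object@lesionalThreshold <= 0 || object@lesionalThreshold >= 1)
    msg <- c(msg, "lesionalThreshold must be in (0, 1)")
  if (object@knnPurity <= 0 || object@knnPurity > 1)
    msg <- c(msg, "knnPurity must be in (0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (object@minLesionalTiles > object@maxTilesPerSlide)
    msg <- c(msg, "minLesionalTiles must be <= maxTilesPerSlide")
  if (object@knnK < 1L) msg <- c(msg, "knnK must be >= 1")
  if (object@hybridWeight < 0 || object@hybridWeight > 1)
    msg <- c(msg, "hybridWeight must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param tileSize pixels per tile side.
#' @param micronsPerPixel physical scale.
#' @param lesionalThreshold probability cutoff for the lesional gate (strict).
#' @param minLesionalTiles minimum gated tiles needed to classify a slide.
#' @param maxTilesPerSlide per-slide tile budget.
#' @param knnK neighbour count of the discretization rule.
#' @param knnPurity purity threshold of the discretization rule.
#' @param alpha chi-square significance level.
#' @param perplexity t-SNE perplexity.
#' @param nCheckNeighbors refinement neighbour count.
#' @param ownClassMin refinement own-class threshold.
#' @param hybridWeight tile-fraction weight of the hybrid score.
#' @param seed integer seed.
#' @return A [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(tileSize = 1024L, micronsPerPixel = 0.504,
                           lesionalThreshold = 0.85, minLesionalTiles = 15L,
                           maxTilesPerSlide = 100L, knnK = 25L,
                           knnPurity = 0.85, alpha = 0.01, perplexity = 30,
                           nCheckNeighbors = 300L, ownClassMin = 0.5,
                           hybridWeight = 0.5, seed = 0L) {
  new("PipelineConfig",
      tileSize = as.integer(tileSize),
      micronsPerPixel = as.numeric(micronsPerPixel),
      lesionalThreshold = as.numeric(lesionalThreshold),
      minLesionalTiles = as.integer(minLesionalTiles),
      maxTilesPerSlide = as.integer(maxTilesPerSlide),
      knnK = as.integer(knnK),
      knnPurity = as.numeric(knnPurity),
      alpha = as.numeric(alpha),
      perplexity = as.numeric(perplexity),
      nCheckNeighbors = as.integer(nCheckNeighbors),
      ownClassMin = as.numeric(ownClassMin),
      hybridWeight = as.numeric(hybridWeight),
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  tile: %d px (%.3f um/px)\n", object@tileSize, object@micronsPerPixel))
  cat(sprintf("  gate: p_lesional > %.2f, min %d tiles, budget %d\n",
              object@lesionalThreshold, object@minLesionalTiles,
              object@maxTilesPerSlide))
  cat(sprintf("  kNN: k=%d, purity >= %.2f; alpha=%.3g; perplexity=%g; seed=%d\n",
              object@knnK, object@knnPurity, object@alpha, object@perplexity,
              object@seed))
})

# ---------------------------------------------------------------------------
# TileSet
# ---------------------------------------------------------------------------

#' A set of image tiles with deep-feature embeddings
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one column per tile. The single assay \code{"features"} stores the
#' embedding (feature dimensions in rows, tiles in columns); per-tile
#' metadata live in \code{colData}: \code{tile_id}, grid position
#' (\code{row}, \code{col}), the reference class \code{label} (reference
#' sets only), the class-probability matrix column \code{classProbs} and the
#' lesional probability \code{p_lesional} (slides only). Slide-level truth
#' metadata (for synthetic slides) and the class-name order are kept in
#' \code{metadata()}.
#'
#' @seealso [tileSet()], [makeReferenceSet()], [makeSlide()]
#' @export
setClass("TileSet", contains = "SummarizedExperiment")

setValidity("TileSet", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!"tile_id" %in% colnames(cd)) return("colData must contain tile_id")
  if (anyDuplicated(cd$tile_id)) msg <- c(msg, "tile_id values must be unique")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if ("classProbs" %in% colnames(cd)) {
    P <- cd$classProbs
    if (ncol(object) > 0) {
      s <- rowSums(P)
      if (any(abs(s - 1) > 1e-6))
        msg <- c(msg, "classProbs rows must sum to 1 (tolerance 1e-6)")
    }
  }
  if ("p_lesional" %in% colnames(cd) && ncol(object) > 0) {
    pl <- cd$p_lesional
    if (any(pl < -1e-12 | pl > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "p_lesional must lie in [0, 1]")
  }
  if (all(c("row", "col") %in% colnames(cd)) && ncol(object) > 0) {
    rc <- paste(cd$row, cd$col)
    if (!anyNA(cd$row) && anyDuplicated(rc))
      msg <- c(msg, "(row, col) grid positions must be unique within a slide")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TileSet
#'
#' @param features numeric matrix of embeddings, tiles in rows.
#' @param tileIds character tile identifiers.
#' @param labels optional class labels (reference sets).
#' @param row,col optional 0-based grid indices.
#' @param classProbs optional tiles x classes probability matrix.
#' @param pLesional optional lesional probabilities.
#' @param classNames class-name order for \code{classProbs}.
#' @param slideId optional slide identifier.
#' @param truth optional named list of truth metadata for synthetic slides.
#' @return A [TileSet-class].
#' @export
tileSet <- function(features, tileIds, labels = NULL, row = NULL, col = NULL,
                    classProbs = NULL, pLesional = NULL, classNames = NULL,
                    slideId = NA_character_, truth = list()) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(tileIds) == n)
  cd <- DataFrame(tile_id = as.character(tileIds))
  if (!is.null(labels)) cd$label <- as.character(labels)
  if (!is.null(row)) cd$row <- as.integer(row)
  if (!is.null(col)) cd$col <- as.integer(col)
  if (!is.null(classProbs)) {
    classProbs <- as.matrix(classProbs)
    stopifnot(nrow(classProbs) == n)
    if (!is.null(classNames)) colnames(classProbs) <- classNames
    cd$classProbs <- classProbs
  }
  if (!is.null(pLesional)) cd$p_lesional <- as.numeric(pLesional)
  fm <- t(features)
  rownames(fm) <- sprintf("f%d", seq_len(ncol(features)) - 1L)
  colnames(fm) <- cd$tile_id
  se <- SummarizedExperiment(assays = list(features = fm), colData = cd)
  md <- list(slideId = slideId, truth = truth, classNames = classNames)
  metadata(se) <- md
  new("TileSet", se)
}

setMethod("show", "TileSet", function(object) {
  md <- metadata(object)
  cat("TileSet with", ncol(object), "tiles x", nrow(object), "feature dims\n")
  if (!is.null(md$slideId) && !is.na(md$slideId))
    cat("  slide:", md$slideId, "\n")
  if ("label" %in% colnames(colData(object))) {
    tb <- table(colData(object)$label)
    cat("  labelled reference tiles over", length(tb), "classes\n")
  }
  if ("p_lesional" %in% colnames(colData(object)))
    cat(sprintf("  p_lesional: median %.3f\n",
                stats::median(colData(object)$p_lesional)))
  tr <- md$truth
  if (length(tr)) cat("  truth:", tr$truthClass, "\n")
})

# ---------------------------------------------------------------------------
# ReferenceMap
# ---------------------------------------------------------------------------

#' Two-dimensional reference embedding of labelled training tiles
#'
#' @slot coords n x 2 matrix of map coordinates.
#' @slot labels class label per reference point.
#' @slot tileIds tile identifier per point.
#' @slot method \code{"tsne"} or \code{"pca"}.
#' @slot params embedding parameters (perplexity, iterations, seed, ...).
#' @slot refined whether neighbourhood refinement has been applied.
#' @slot provenance per-class point counts before/after refinement.
#' @slot pca for PCA maps, the centring vector and 2-column rotation so that
#'   projection of new points is exactly reproducible.
#' @seealso [buildReferenceMap()], [refineReferenceMap()]
#' @export
setClass("ReferenceMap", representation(
  coords = "matrix",
  labels = "character",
  tileIds = "character",
  method = "character",
  params = "list",
  refined = "logical",
  provenance = "data.frame",
  pca = "list"
))

setValidity("ReferenceMap", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  n <- nrow(object@coords)
  if (length(object@labels) != n || length(object@tileIds) != n)
    msg <- c(msg, "labels and tileIds must match coords rows")
  if (anyDuplicated(object@tileIds)) msg <- c(msg, "tileIds must be unique")
  if (!object@method %in% c("tsne", "pca"))
    msg <- c(msg, "method must be 'tsne' or 'pca'")
  if (n > 0 && any(table(object@labels) < 1L))
    msg <- c(msg, "every class must retain at least one point")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceMap", function(object) {
  cat(sprintf("ReferenceMap (%s%s): %d points, %d classes\n",
              object@method, if (object@refined) ", refined" else "",
              nrow(object@coords), length(unique(object@labels))))
  if (object@refined && nrow(object@provenance)) {
    rem <- sum(object@provenance$before - object@provenance$after)
    cat("  refinement removed", rem, "points\n")
  }
})

# ---------------------------------------------------------------------------
# SlideDecision
# ---------------------------------------------------------------------------

#' Statistically driven slide-level verdict
#'
#' The outcome of the iterative chi-square decision procedure applied to a
#' slide's tile contingency table: a single \code{DIAGNOSIS}, a
#' \code{DIFFERENTIAL} list of statistically indistinguishable classes,
#' \code{UNDEFINED} for anomalous slides dominated by outlier tiles, or
#' \code{INSUFFICIENT_LESIONAL} when too few tiles pass the lesional gate.
#'
#' @slot status one of \code{"DIAGNOSIS"}, \code{"DIFFERENTIAL"},
#'   \code{"UNDEFINED"}, \code{"INSUFFICIENT_LESIONAL"}.
#' @slot classes retained classes: a singleton for a diagnosis, two or more
#'   for a differential (count-descending), empty otherwise.
#' @slot trail per-iteration record of the test: remaining categories,
#'   counts, chi-square statistic, degrees of freedom, p-value and the
#'   removed category.
#' @slot alpha significance level used.
#' @seealso [decideSlide()]
#' @export
setClass("SlideDecision", representation(
  status = "character",
  classes = "character",
  trail = "data.frame",
  alpha = "numeric"
))

setValidity("SlideDecision", function(object) {
  ok <- c("DIAGNOSIS", "DIFFERENTIAL", "UNDEFINED", "INSUFFICIENT_LESIONAL")
  msg <- character(0)
  if (!object@status %in% ok)
    msg <- c(msg, paste("status must be one of:", paste(ok, collapse = ", ")))
  if (object@status == "DIAGNOSIS" && length(object@classes) != 1L)
    msg <- c(msg, "DIAGNOSIS requires exactly one class")
  if (object@status == "DIFFERENTIAL" && length(object@classes) < 2L)
    msg <- c(msg, "DIFFERENTIAL requires >= 2 classes")
  if (object@status %in% c("UNDEFINED", "INSUFFICIENT_LESIONAL") &&
      length(object@classes) != 0L)
    msg <- c(msg, "uncertainty statuses carry no classes")
  if (OUTLIER_LABEL %in% object@classes)
    msg <- c(msg, "classes may never contain the outlier label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SlideDecision", function(object) {
  cat("SlideDecision:", object@status)
  if (length(object@classes))
    cat(" [", paste(object@classes, collapse = ", "), "]")
  cat("  (alpha =", object@alpha, ")\n")
  if (nrow(object@trail)) {
    cat("  trail:\n")
    for (i in seq_len(nrow(object@trail))) {
      r <- object@trail[i, ]
      cat(sprintf("    %d: {%s} X2=%.3g df=%d p=%.3g%s\n", r$iteration,
                  r$classes, r$statistic, r$df, r$p.value,
                  if (is.na(r$removed)) "" else paste0(" -> drop ", r$removed)))
    }
  }
})

# ---------------------------------------------------------------------------
# SlideReport
# ---------------------------------------------------------------------------

#' Full per-slide classification report
#'
#' Bundles every output of [classifySlide()] for one slide: the map-based
#' decision with its statistical trail, the probability-score baseline, the
#' combined (concordance) call, the hybrid blended scores, the tile
#' assignments and the contingency table.
#'
#' @slot slideId slide identifier.
#' @slot decision the [SlideDecision-class].
#' @slot assignments per-tile assignment table
#'   (\code{tile_id}, \code{call}, \code{purity}).
#' @slot contingency named tile counts per called category.
#' @slot tileFractions per-class assigned-tile fractions (outliers excluded).
#' @slot outlierFraction fraction of assigned tiles called outlier.
#' @slot probMeans mean softmax probability per class over gated tiles.
#' @slot probTop top class of the probability baseline.
#' @slot combined concordance call: the shared class or \code{"UNDEFINED"}.
#' @slot hybrid blended score per class.
#' @slot nTiles tile counts through the pipeline stages (input, gated,
#'   sampled).
#' @slot review up to five highest-probability lesional tiles retained for
#'   manual review when a slide is not classifiable.
#' @export
setClass("SlideReport", representation(
  slideId = "character",
  decision = "SlideDecision",
  assignments = "DataFrame",
  contingency = "numeric",
  tileFractions = "numeric",
  outlierFraction = "numeric",
  probMeans = "numeric",
  probTop = "character",
  combined = "character",
  hybrid = "numeric",
  nTiles = "numeric",
  review = "character"
))

setMethod("show", "SlideReport", function(object) {
  cat("SlideReport for slide", object@slideId, "\n")
  cat("  tiles: ", paste(names(object@nTiles), object@nTiles,
                         sep = "=", collapse = ", "), "\n")
  cat("  map verdict:", object@decision@status,
      if (length(object@decision@classes))
        paste0("[", paste(object@decision@classes, collapse = ", "), "]")
      else "", "\n")
  if (!is.na(object@probTop))
    cat("  probability top class:", object@probTop, "\n")
  cat("  combined:", object@combined, "\n")
})

# ---------------------------------------------------------------------------
# EvaluationReport
# ---------------------------------------------------------------------------

#' Evaluation of slide predictions against ground truth
#'
#' @slot perSlide one row per slide and method: prediction, status, truth
#'   and outcome (\code{CORRECT}, \code{TYPE_A}, \code{TYPE_B},
#'   \code{TYPE_C} or \code{EXCLUDED}).
#' @slot aucByMethod macro-averaged one-vs-rest AUC per scoring method.
#' @slot sweeps cutoff sweep curves per mode
#'   (\code{cutoff}, \code{accuracy}, \code{error}, \code{coverage}).
#' @seealso [evaluateSlides()]
#' @export
setClass("EvaluationReport", representation(
  perSlide = "DataFrame",
  aucByMethod = "numeric",
  sweeps = "list"
))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", length(unique(object@perSlide$slide_id)),
      "slides,", length(unique(object@perSlide$method)), "methods\n")
  if (length(object@aucByMethod)) {
    cat("  AUC:", paste(names(object@aucByMethod),
                        sprintf("%.3f", object@aucByMethod),
                        sep = "=", collapse = ", "), "\n")
  }
  tb <- table(object@perSlide$method, object@perSlide$outcome)
  print(tb)
})
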