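#' @include AllClasses.R
NULL

#' Mock embedding provider
#'
#' The pipeline consumes per-tile feature vectors, class probabilities and a
#' lesional probability through a small provider contract, so that any
#' trained network can be wired in by supplying the same three outputs. The
#' mock provider implements the contract from a fixture geometry (class
#' means): features of fixture tiles pass through unchanged, class
#' probabilities are the squared-distance softmax against the class means,
#' and the lesional probability is the summed mass of the lesion classes
#' (the two-model design collapses the five tumour classes into one "lesion"
#' super-class for gating).
#'
#' @slot classMeans nClasses x featureDim matrix of cluster centres.
#' @slot classNames ordered class labels (probability index i corresponds to
#'   \code{classNames[i]} for the life of a run).
#' @slot lesionClassIds indices of lesional classes.
#' @slot temperature softmax temperature.
#' @seealso [mockProvider()], [embedTile()], [classProbs()],
#'   [lesionalProb()]
#' @export
setClass("MockEmbeddingProvider", representation(
  classMeans = "matrix",
  classNames = "character",
  lesionClassIds = "integer",
  temperature = "numeric"
))

setValidity("MockEmbeddingProvider", function(object) {
  msg <- character(0)
  if (nrow(object@classMeans) != length(object@classNames))
    msg <- c(msg, "classMeans rows must match classNames")
  if (length(object@classNames) < 2L) msg <- c(msg, "need >= 2 classes")
  ids <- object@lesionClassIds
  if (!length(ids) || any(ids < 1L | ids > length(object@classNames)))
    msg <- c(msg, "lesionClassIds out of range")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a mock provider from a fixture configuration
#'
#' @param config a [FixtureConfig-class].
#' @return A [MockEmbeddingProvider-class].
#' @export
mockProvider <- function(config) {
  new("MockEmbeddingProvider",
      classMeans = placeClassMeans(config),
      classNames = config@classNames,
      lesionClassIds = config@lesionClassIds,
      temperature = config@softmaxTemperature)
}

setMethod("show", "MockEmbeddingProvider", function(object) {
  cat("MockEmbeddingProvider:", length(object@classNames), "classes,",
      ncol(object@classMeans), "feature dims\n")
})

.provider_feature <- function(provider, tile) {
  x <- as.numeric(tile)
  if (length(x) != ncol(provider@classMeans))
    stop("malformed tile", if (!is.null(names(tile))) paste0(" '", names(tile)[1], "'"),
         ": expected a feature vector of length ", ncol(provider@classMeans),
         ", got ", length(x))
  x
}

#' Provider contract: feature embedding of a tile
#'
#' For the mock provider the embedding of a fixture tile is the tile's
#' stored feature vector, unchanged. Identical tiles always give identical
#' vectors (determinism is part of the contract and asserted by the
#' pipeline).
#'
#' @param provider a provider object.
#' @param tile a numeric feature vector (mock provider) or one column of a
#'   [TileSet-class].
#' @return numeric feature vector.
#' @export
setGeneric("embedTile", function(provider, tile) standardGeneric("embedTile"))

#' @rdname embedTile
#' @export
setMethod("embedTile", "MockEmbeddingProvider", function(provider, tile) {
  .provider_feature(provider, tile)
})

#' @describeIn embedTile class-probability vector of a tile (sums to 1).
#' @export
setMethod("classProbs", "MockEmbeddingProvider", function(x, tile, ...) {
  f <- .provider_feature(x, tile)
  softmax_class_probs(f, x@classMeans, x@temperature)
})

#' Provider contract: lesional probability of a tile
#'
#' @inheritParams embedTile
#' @return scalar in \[0, 1\].
#' @export
setGeneric("lesionalProb", function(provider, tile) standardGeneric("lesionalProb"))

#' @rdname lesionalProb
#' @export
setMethod("lesionalProb", "MockEmbeddingProvider", function(provider, tile) {
  p <- classProbs(provider, tile)
  sum(p[provider@lesionClassIds])
})

#' Validate an externally supplied probability vector
#'
#' Accepts vectors whose sum deviates from 1 by at most \code{tol}
#' (renormalizing them); rejects anything further off, which signals a
#' malformed provider rather than floating-point noise.
#'
#' @param p numeric vector of class probabilities.
#' @param tol tolerated deviation of \code{sum(p)} from 1.
#' @return the (renormalized) probability vector.
#' @export
validateProbVector <- function(p, tol = 1e-6) {
  if (any(p < -tol)) stop("probability vector has negative entries")
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop(sprintf("probability vector sums to %.8f (tolerance %g)", s, tol))
  p / s
}
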