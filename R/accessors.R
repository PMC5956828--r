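#' @include AllClasses.R
NULL

#' Tile-level accessors
#'
#' Convenience accessors for [TileSet-class] content. \code{tileFeatures}
#' returns the embedding with tiles in rows (the transpose of the stored
#' assay); \code{classProbs} the tiles x classes probability matrix;
#' \code{pLesional} the lesional probability; \code{tileLabels} the
#' reference class labels; \code{tileIds} the identifiers; \code{slideId}
#' the slide identifier; \code{slideTruth} the truth metadata list of a
#' synthetic slide.
#'
#' @param x a [TileSet-class].
#' @return See individual descriptions.
#' @name tile-accessors
NULL

#' @rdname tile-accessors
#' @export
setGeneric("tileFeatures", function(x) standardGeneric("tileFeatures"))

#' @rdname tile-accessors
#' @export
setMethod("tileFeatures", "TileSet", function(x) t(assay(x, "features")))

#' @rdname tile-accessors
#' @export
setGeneric("classProbs", function(x, ...) standardGeneric("classProbs"))

#' @rdname tile-accessors
#' @export
setMethod("classProbs", "TileSet", function(x, ...) {
  cd <- colData(x)
  if (!"classProbs" %in% colnames(cd)) return(NULL)
  P <- cd$classProbs
  rownames(P) <- cd$tile_id
  P
})

#' @rdname tile-accessors
#' @export
setGeneric("pLesional", function(x) standardGeneric("pLesional"))

#' @rdname tile-accessors
#' @export
setMethod("pLesional", "TileSet", function(x) {
  cd <- colData(x)
  if (!"p_lesional" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$p_lesional, cd$tile_id)
})

#' @rdname tile-accessors
#' @export
setGeneric("tileLabels", function(x) standardGeneric("tileLabels"))

#' @rdname tile-accessors
#' @export
setMethod("tileLabels", "TileSet", function(x) {
  cd <- colData(x)
  if (!"label" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$label, cd$tile_id)
})

#' @rdname tile-accessors
#' @export
setGeneric("tileIds", function(x) standardGeneric("tileIds"))

#' @rdname tile-accessors
#' @export
setMethod("tileIds", "TileSet", function(x) colData(x)$tile_id)

#' @rdname tile-accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname tile-accessors
#' @export
setMethod("slideId", "TileSet", function(x) metadata(x)$slideId)

#' @rdname tile-accessors
#' @export
setGeneric("slideTruth", function(x) standardGeneric("slideTruth"))

#' @rdname tile-accessors
#' @export
setMethod("slideTruth", "TileSet", function(x) metadata(x)$truth)

#' Map-level accessors
#'
#' \code{mapCoords} returns the n x 2 coordinate matrix of a
#' [ReferenceMap-class]; \code{mapLabels} the class label per point;
#' \code{mapMethod} the embedding method.
#'
#' @param x a [ReferenceMap-class].
#' @name map-accessors
NULL

#' @rdname map-accessors
#' @export
setGeneric("mapCoords", function(x) standardGeneric("mapCoords"))

#' @rdname map-accessors
#' @export
setMethod("mapCoords", "ReferenceMap", function(x) x@coords)

#' @rdname map-accessors
#' @export
setGeneric("mapLabels", function(x) standardGeneric("mapLabels"))

#' @rdname map-accessors
#' @export
setMethod("mapLabels", "ReferenceMap", function(x) x@labels)

#' @rdname map-accessors
#' @export
setGeneric("mapMethod", function(x) standardGeneric("mapMethod"))

#' @rdname map-accessors
#' @export
setMethod("mapMethod", "ReferenceMap", function(x) x@method)

#' Decision accessors
#'
#' \code{decisionStatus} returns the verdict status of a
#' [SlideDecision-class]; \code{decisionClasses} the retained class list;
#' \code{decisionTrail} the per-iteration chi-square record.
#'
#' @param x a [SlideDecision-class] or [SlideReport-class].
#' @name decision-accessors
NULL

#' @rdname decision-accessors
#' @export
setGeneric("decisionStatus", function(x) standardGeneric("decisionStatus"))

#' @rdname decision-accessors
#' @export
setMethod("decisionStatus", "SlideDecision", function(x) x@status)

#' @rdname decision-accessors
#' @export
setMethod("decisionStatus", "SlideReport", function(x) x@decision@status)

#' @rdname decision-accessors
#' @export
setGeneric("decisionClasses", function(x) standardGeneric("decisionClasses"))

#' @rdname decision-accessors
#' @export
setMethod("decisionClasses", "SlideDecision", function(x) x@classes)

#' @rdname decision-accessors
#' @export
setMethod("decisionClasses", "SlideReport", function(x) x@decision@classes)

#' @rdname decision-accessors
#' @export
setGeneric("decisionTrail", function(x) standardGeneric("decisionTrail"))

#' @rdname decision-accessors
#' @export
setMethod("decisionTrail", "SlideDecision", function(x) x@trail)

#' @rdname decision-accessors
#' @export
setMethod("decisionTrail", "SlideReport", function(x) x@decision@trail)
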