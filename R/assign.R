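#' @include AllClasses.R
NULL

#' Discretize one query tile on the 2-D map
#'
#' Applies the nearest-neighbour purity rule: the tile's \code{k} nearest
#' reference points (2-D Euclidean; query tiles never vote) are examined,
#' and if at least a fraction \code{purity} of them carry a single class
#' label the tile is discretized to that class; otherwise it is an outlier
#' / anomalous data point. Distance ties at the k-th neighbour are broken
#' by reference point order, and purity ties between classes by label
#' order, so calls are fully deterministic.
#'
#' @param queryPoint numeric length-2 map coordinates of the tile.
#' @param refCoords n x 2 reference coordinates.
#' @param refLabels class label per reference point.
#' @param k neighbours examined (default 25).
#' @param purity modal-class fraction required (default 0.85; the
#'   comparison is \code{>=}).
#' @param tileId identifier carried into the result.
#' @return list with \code{tile_id}, \code{call} (class or
#'   \code{OUTLIER_LABEL}), \code{purity} (modal fraction) and
#'   \code{neighborCounts} (named counts over the k neighbours).
#' @examples
#' ref <- rbind(matrix(0, 22, 2), matrix(10, 3, 2))
#' assignTile(c(0, 0), ref, rep(c("glioma", "meningioma"), c(22, 3)))$call
#' @export
assignTile <- function(queryPoint, refCoords, refLabels, k = 25L,
                       purity = 0.85, tileId = NA_character_) {
  n <- nrow(refCoords)
  if (n < k)
    stop("reference has ", n, " points but k = ", k, " neighbours requested")
  nb <- knn_indices(as.numeric(queryPoint), refCoords, k)
  lev <- sort(unique(refLabels))
  counts <- table(factor(refLabels[nb], levels = lev))
  counts <- counts[counts > 0L]
  top <- which.max(counts)  # ties broken by (sorted) label order
  frac <- as.numeric(counts[top]) / k
  call <- if (frac >= purity) names(counts)[top] else OUTLIER_LABEL
  list(tile_id = tileId, call = call, purity = frac,
       neighborCounts = stats::setNames(as.integer(counts), names(counts)))
}

#' Discretize all query tiles of a slide
#'
#' Vector version of [assignTile()] over a matrix of query coordinates.
#'
#' @param queryCoords m x 2 matrix of query map coordinates.
#' @param refCoords n x 2 reference coordinates.
#' @param refLabels class label per reference point.
#' @param k,purity see [assignTile()].
#' @param tileIds identifiers (default positional).
#' @return A [S4Vectors::DataFrame] with columns \code{tile_id},
#'   \code{call}, \code{purity}; the per-tile neighbour count matrix is
#'   attached as \code{metadata()$neighborCounts}.
#' @export
assignTiles <- function(queryCoords, refCoords, refLabels, k = 25L,
                        purity = 0.85, tileIds = NULL) {
  queryCoords <- as.matrix(queryCoords)
  m <- nrow(queryCoords)
  if (is.null(tileIds)) tileIds <- sprintf("tile_%04d", seq_len(m))
  lev <- sort(unique(refLabels))
  counts <- matrix(0L, m, length(lev), dimnames = list(tileIds, lev))
  calls <- character(m)
  pur <- numeric(m)
  for (i in seq_len(m)) {
    a <- assignTile(queryCoords[i, ], refCoords, refLabels, k, purity,
                    tileIds[i])
    calls[i] <- a$call
    pur[i] <- a$purity
    counts[i, names(a$neighborCounts)] <- a$neighborCounts
  }
  out <- DataFrame(tile_id = tileIds, call = calls, purity = pur)
  metadata(out) <- list(neighborCounts = counts, k = as.integer(k),
                        purityThreshold = purity)
  out
}

#' Tabulate tile assignments into a contingency table
#'
#' @param assignments result of [assignTiles()] (or any object with a
#'   \code{call} column / character vector of calls).
#' @return named integer vector of tile counts per called category
#'   (including the outlier category); zero-count classes are omitted.
#' @export
tabulateAssignments <- function(assignments) {
  calls <- if (is.character(assignments)) assignments else assignments$call
  if (length(calls) == 0L) stop("no assignments to tabulate")
  tb <- table(calls)
  stats::setNames(as.integer(tb), names(tb))
}
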