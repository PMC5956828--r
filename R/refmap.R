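#' @include AllClasses.R
NULL

## Run the seeded t-SNE backend. Distances are taken in the original
## feature space (no PCA pre-reduction): with high-dimensional CNN-style
## features the within-class variance is structural, and discarding it
## artificially re-separates the classes.
.run_tsne <- function(X, perplexity, seed, maxIter = 1000L, theta = 0.5) {
  if (nrow(X) - 1 < 3 * perplexity)
    stop("too few points (", nrow(X), ") for perplexity ", perplexity,
         "; need at least 3 * perplexity + 1")
  with_seed(seed, {
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = theta,
                 max_iter = as.integer(maxIter), pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE,
                 num_threads = 1L)$Y
  })
}

#' Build the 2-D reference map of labelled training tiles
#'
#' Embeds the reference tile features on a plane with t-SNE (default) or
#' PCA. The t-SNE map is the discretization substrate of the whole
#' workflow: class clusters on this plane define the neighbourhoods against
#' which query tiles are later classified. PCA mode projects onto the top
#' two principal components of the centred feature matrix and is provided
#' as the linear comparison method.
#'
#' @param reference a labelled [TileSet-class] (see [makeReferenceSet()]),
#'   or a feature matrix with tiles in rows.
#' @param labels class labels (required when \code{reference} is a matrix).
#' @param method \code{"tsne"} or \code{"pca"}.
#' @param perplexity t-SNE perplexity.
#' @param seed seed for the stochastic t-SNE optimisation (ignored by PCA,
#'   which is deterministic).
#' @param maxIter t-SNE gradient-descent iterations.
#' @param theta Barnes-Hut accuracy parameter.
#' @return A [ReferenceMap-class].
#' @export
buildReferenceMap <- function(reference, labels = NULL, method = c("tsne", "pca"),
                              perplexity = 30, seed = 0L, maxIter = 1000L,
                              theta = 0.5) {
  method <- match.arg(method)
  if (is(reference, "TileSet")) {
    X <- tileFeatures(reference)
    labels <- unname(tileLabels(reference))
    ids <- tileIds(reference)
  } else {
    X <- as.matrix(reference)
    ids <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("ref_%05d", seq_len(nrow(X)))
  }
  if (is.null(labels)) stop("reference labels are required")
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  pca <- list()
  if (method == "pca") {
    ctr <- colMeans(X)
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
    Y <- pr$x[, 1:2, drop = FALSE]
    pca <- list(center = ctr, rotation = pr$rotation[, 1:2, drop = FALSE])
  } else {
    Y <- .run_tsne(X, perplexity, seed, maxIter, theta)
  }
  colnames(Y) <- c("dim1", "dim2")
  prov <- as.data.frame(table(labels), stringsAsFactors = FALSE)
  names(prov) <- c("class", "before")
  prov$after <- prov$before
  new("ReferenceMap", coords = unname(Y), labels = as.character(labels),
      tileIds = ids, method = method,
      params = list(perplexity = perplexity, seed = as.integer(seed),
                    maxIter = as.integer(maxIter), theta = theta),
      refined = FALSE, provenance = prov, pca = pca)
}

#' Remove deviating points from a reference map
#'
#' Quality-control pass over the training map: each point is compared to
#' its nearest \code{nCheckNeighbors} reference neighbours (2-D Euclidean)
#' and removed when the fraction belonging to its own labelled class falls
#' below \code{ownClassMin}. This prunes mislabelled training tiles and
#' tiles containing features of several classes. A single pass is made;
#' on clean maps the operation is idempotent.
#'
#' The default neighbour count (300) presumes per-class reference sizes of
#' several hundred tiles; scale it down together with the reference set
#' (a class of n points can never reach an own-class fraction of 0.5 among
#' many more than 2n neighbours).
#'
#' @param map a [ReferenceMap-class].
#' @param nCheckNeighbors neighbours examined per point.
#' @param ownClassMin minimum own-class fraction to retain a point.
#' @return the refined [ReferenceMap-class] (refinement counts in
#'   \code{provenance}).
#' @export
refineReferenceMap <- function(map, nCheckNeighbors = 300L, ownClassMin = 0.5) {
  n <- nrow(map@coords)
  if (n <= nCheckNeighbors)
    stop("map has ", n, " points; needs more than nCheckNeighbors = ",
         nCheckNeighbors)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d2 <- sqdist_to(map@coords[i, ], map@coords)
    d2[i] <- Inf
    nb <- order(d2, seq_len(n))[seq_len(nCheckNeighbors)]
    frac <- mean(map@labels[nb] == map@labels[i])
    keep[i] <- frac >= ownClassMin
  }
  dropped <- table(factor(map@labels[!keep], levels = unique(map@labels)))
  remaining <- table(factor(map@labels[keep], levels = unique(map@labels)))
  if (any(remaining == 0L))
    stop("refinement would remove every point of class(es): ",
         paste(names(remaining)[remaining == 0L], collapse = ", "))
  prov <- map@provenance
  prov$after <- as.integer(remaining[match(prov$class, names(remaining))])
  new("ReferenceMap", coords = map@coords[keep, , drop = FALSE],
      labels = map@labels[keep], tileIds = map@tileIds[keep],
      method = map@method,
      params = c(map@params, list(nCheckNeighbors = as.integer(nCheckNeighbors),
                                  ownClassMin = ownClassMin)),
      refined = TRUE, provenance = prov, pca = map@pca)
}

#' Restrict a reference tile set to the points retained by a refined map
#'
#' @param reference the original [TileSet-class].
#' @param map a refined [ReferenceMap-class] built from it.
#' @return the subset [TileSet-class].
#' @export
applyRefinement <- function(reference, map) {
  reference[, tileIds(reference) %in% map@tileIds]
}

#' Jointly embed reference and query tiles
#'
#' Re-runs the 2-D embedding from scratch on the union of reference and
#' query features, as done once per slide: query tiles participate in the
#' optimisation, but class labels are carried only by the reference points.
#' With a fixed seed the result is deterministic. In PCA mode queries are
#' projected onto the reference components (exactly reproducible, no seed
#' involved).
#'
#' @param reference labelled [TileSet-class] or feature matrix.
#' @param query query feature matrix (tiles in rows) or [TileSet-class].
#' @param labels reference labels when \code{reference} is a matrix.
#' @param method \code{"tsne"} or \code{"pca"}.
#' @param perplexity t-SNE perplexity.
#' @param seed seed of the joint optimisation.
#' @param maxIter t-SNE iterations.
#' @param theta Barnes-Hut accuracy.
#' @return list with \code{reference} (n_ref x 2), \code{query}
#'   (n_query x 2) and \code{labels} (reference labels).
#' @export
embedWithQueries <- function(reference, query, labels = NULL,
                             method = c("tsne", "pca"), perplexity = 30,
                             seed = 0L, maxIter = 1000L, theta = 0.5) {
  method <- match.arg(method)
  if (is(reference, "TileSet")) {
    X <- tileFeatures(reference)
    labels <- unname(tileLabels(reference))
  } else X <- as.matrix(reference)
  if (is(query, "TileSet")) query <- tileFeatures(query)
  query <- as.matrix(query)
  if (nrow(query) < 1L) stop("query set is empty")
  if (ncol(query) != ncol(X))
    stop("feature dimension mismatch: reference has ", ncol(X),
         ", query has ", ncol(query))
  if (is.null(labels)) stop("reference labels are required")
  nR <- nrow(X)
  if (method == "pca") {
    ctr <- colMeans(X)
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
    refY <- pr$x[, 1:2, drop = FALSE]
    qY <- sweep(query, 2, ctr) %*% pr$rotation[, 1:2, drop = FALSE]
  } else {
    Y <- .run_tsne(rbind(X, query), perplexity, seed, maxIter, theta)
    refY <- Y[seq_len(nR), , drop = FALSE]
    qY <- Y[-seq_len(nR), , drop = FALSE]
  }
  list(reference = unname(refY), query = unname(qY),
       labels = as.character(labels))
}

#' Serialize a reference map to JSON
#'
#' @param map a [ReferenceMap-class].
#' @param file path of the JSON file to write.
#' @return \code{file}, invisibly.
#' @export
writeReferenceMap <- function(map, file) {
  obj <- list(
    method = map@method,
    params = map@params,
    refined = map@refined,
    provenance = map@provenance,
    points = data.frame(tile_id = map@tileIds, label = map@labels,
                        dim1 = map@coords[, 1], dim2 = map@coords[, 2])
  )
  if (length(map@pca))
    obj$pca <- list(center = unname(map@pca$center),
                    rotation = unname(map@pca$rotation))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a reference map from JSON
#'
#' @param file path written by [writeReferenceMap()].
#' @return A [ReferenceMap-class].
#' @export
readReferenceMap <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  pca <- list()
  if (!is.null(obj$pca))
    pca <- list(center = as.numeric(obj$pca$center),
                rotation = matrix(unlist(obj$pca$rotation),
                                  ncol = 2))
  new("ReferenceMap",
      coords = cbind(obj$points$dim1, obj$points$dim2),
      labels = obj$points$label, tileIds = obj$points$tile_id,
      method = obj$method, params = as.list(obj$params),
      refined = isTRUE(obj$refined),
      provenance = as.data.frame(obj$provenance), pca = pca)
}

#' Plot a reference map with optional query overlay
#'
#' Draws the class-coloured reference scatter with query tiles overlaid as
#' red diamonds, the standard visual output of the workflow.
#'
#' @param map a [ReferenceMap-class].
#' @param query optional n x 2 matrix of query coordinates.
#' @param file optional PNG path; when given the plot is written to file.
#' @param main plot title.
#' @return invisibly, the palette used.
#' @export
plotReferenceMap <- function(map, query = NULL, file = NULL, main = NULL) {
  classes <- sort(unique(map@labels))
  pal <- stats::setNames(
    grDevices::hcl.colors(max(3L, length(classes)), "Dark 3")[seq_along(classes)],
    classes)
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  graphics::plot(map@coords, col = pal[map@labels], pch = 16, cex = 0.5,
                 xlab = "dim 1", ylab = "dim 2",
                 main = if (is.null(main)) sprintf("%s reference map", map@method)
                        else main)
  if (!is.null(query))
    graphics::points(query, pch = 18, cex = 1.2, col = "red")
  graphics::legend("topright", legend = classes, col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  if (!is.null(file)) grDevices::dev.off()
  invisible(pal)
}
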