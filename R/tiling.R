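#' @include AllClasses.R
NULL

#' Tile an image into a fixed-size grid
#'
#' Computes the non-overlapping grid of full \code{tileSize x tileSize}
#' tiles covering an image, in row-major order. Pixel bounds are 0-based and
#' half-open (\code{[r*s, (r+1)*s)}); partial tiles at the right/bottom
#' edges are dropped, since downstream feature extractors expect fixed-size
#' inputs.
#'
#' @param image either a raster (matrix or array with dim
#'   \code{c(height, width, ...)}) or an integer vector
#'   \code{c(width, height)} in pixels.
#' @param tileSize tile edge length in pixels.
#' @return data.frame with columns \code{row}, \code{col} (0-based grid
#'   indices), \code{x0}, \code{x1}, \code{y0}, \code{y1} (half-open pixel
#'   bounds). Zero rows, with a warning, when the image is smaller than one
#'   tile in either dimension.
#' @examples
#' nrow(tileImage(c(4096, 2048), 1024))   # 8 tiles
#' @export
tileImage <- function(image, tileSize = 1024L) {
  if (is.matrix(image) || is.array(image)) {
    height <- dim(image)[1]
    width <- dim(image)[2]
  } else {
    stopifnot(length(image) == 2L)
    width <- image[1]
    height <- image[2]
  }
  if (width < 1 || height < 1) stop("image dimensions must be >= 1 pixel")
  nCols <- width %/% tileSize
  nRows <- height %/% tileSize
  if (nCols < 1 || nRows < 1) {
    warning(sprintf("image (%d x %d) is smaller than one %d-pixel tile; no tiles produced",
                    width, height, tileSize))
    return(data.frame(row = integer(0), col = integer(0),
                      x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0)))
  }
  g <- expand.grid(col = seq_len(nCols) - 1L, row = seq_len(nRows) - 1L)
  data.frame(row = g$row, col = g$col,
             x0 = g$col * tileSize, x1 = (g$col + 1L) * tileSize,
             y0 = g$row * tileSize, y1 = (g$row + 1L) * tileSize)
}

#' Gate tiles by lesional probability
#'
#' Keeps tiles whose lesional probability is strictly greater than the
#' threshold, preserving order. The strict inequality is deliberate: a tile
#' scoring exactly at the threshold is not considered enriched.
#'
#' @param tiles a [TileSet-class] with a \code{p_lesional} column.
#' @param threshold probability cutoff (default 0.85).
#' @return the gated [TileSet-class] subset.
#' @export
gateLesional <- function(tiles, threshold = 0.85) {
  pl <- pLesional(tiles)
  if (is.null(pl)) stop("tiles carry no p_lesional column")
  tiles[, pl > threshold]
}

#' Randomly sample tiles up to the per-slide budget
#'
#' If the input holds no more tiles than the budget, all are returned
#' unchanged; otherwise a seeded uniform sample without replacement of
#' exactly \code{maxTiles} tiles is taken (original order preserved).
#'
#' @param tiles a [TileSet-class].
#' @param maxTiles per-slide tile budget.
#' @param seed integer seed.
#' @return sampled [TileSet-class].
#' @export
sampleTiles <- function(tiles, maxTiles = 100L, seed = 0L) {
  stopifnot(maxTiles >= 1L)
  n <- ncol(tiles)
  if (n <= maxTiles) return(tiles)
  keep <- with_seed(seed, sort(sample.int(n, maxTiles)))
  tiles[, keep]
}

#' Enforce the minimum-lesional-tile rule
#'
#' Slides with fewer gated tiles than the minimum are not classified;
#' instead a handful (up to 5) of the highest-probability lesional tiles are
#' handed over for manual review by the pathologist.
#'
#' @param tiles gated (and possibly sampled) [TileSet-class].
#' @param minTiles minimum tile count required to proceed (default 15; a
#'   laxer variant uses 5).
#' @return list with \code{status} (\code{"PROCEED"} or
#'   \code{"INSUFFICIENT_LESIONAL"}) and \code{review}, the tile ids of up
#'   to 5 top-scoring lesional tiles (empty when proceeding).
#' @export
checkMinTiles <- function(tiles, minTiles = 15L) {
  n <- ncol(tiles)
  if (n >= minTiles)
    return(list(status = "PROCEED", review = character(0)))
  pl <- pLesional(tiles)
  review <- character(0)
  if (n > 0) {
    ord <- order(-pl, seq_len(n))
    review <- tileIds(tiles)[ord[seq_len(min(5L, n))]]
  }
  list(status = "INSUFFICIENT_LESIONAL", review = review)
}

#' Default class-activation-map palette
#'
#' A colour per trained class plus dedicated colours for outlier and ungated
#' tiles.
#'
#' @param classes character vector of class names.
#' @return named vector of hex colours.
#' @export
camPalette <- function(classes) {
  base <- grDevices::hcl.colors(max(3L, length(classes)), "Dark 3")
  cols <- stats::setNames(base[seq_along(classes)], classes)
  c(cols, stats::setNames(c("#404040", "#D9D9D9"),
                          c(OUTLIER_LABEL, "ungated")))
}

#' Render a class-activation map by tile reassembly
#'
#' Reassembles per-tile class calls into a slide-level overlay: each tile's
#' pixel footprint is filled with its class colour, giving a global view of
#' lesion localization. Also reports the per-class area fractions over
#' called tiles.
#'
#' @param geometries tile geometry data.frame as returned by [tileImage()].
#' @param calls character class call per geometry row (a trained class,
#'   \code{OUTLIER_LABEL}, or \code{"ungated"}).
#' @param imageDim \code{c(width, height)} of the target image in pixels;
#'   defaults to the bounding box of the geometries.
#' @param palette named colour vector; defaults to [camPalette()].
#' @param file optional path; when given the overlay is written as PNG.
#' @param scale rendering scale in pixels per image pixel (the overlay is
#'   drawn at \code{dim * scale}; tiles of 1024 px rarely need full
#'   resolution).
#' @return list with \code{raster} (height x width x 3 RGB array in
#'   \[0, 1\]) and \code{fractions}, a data.frame \code{class},
#'   \code{fraction} over called (non-ungated) tiles, summing to 1.
#' @export
renderCAM <- function(geometries, calls, imageDim = NULL, palette = NULL,
                      file = NULL, scale = NULL) {
  stopifnot(nrow(geometries) == length(calls))
  if (is.null(imageDim)) {
    imageDim <- if (nrow(geometries)) c(max(geometries$x1), max(geometries$y1))
                else c(1L, 1L)
  }
  if (nrow(geometries) &&
      (max(geometries$x1) > imageDim[1] || max(geometries$y1) > imageDim[2] ||
       min(geometries$x0) < 0 || min(geometries$y0) < 0))
    stop("tile geometry lies outside the image bounds")
  if (is.null(palette)) {
    cls <- setdiff(unique(calls), c(OUTLIER_LABEL, "ungated"))
    palette <- camPalette(sort(cls))
  }
  if (is.null(scale)) scale <- min(1, 256 / max(imageDim))
  W <- max(1L, as.integer(round(imageDim[1] * scale)))
  H <- max(1L, as.integer(round(imageDim[2] * scale)))
  img <- array(1, dim = c(H, W, 3))
  for (i in seq_len(nrow(geometries))) {
    cl <- calls[i]
    colhex <- if (cl %in% names(palette)) palette[[cl]] else "#000000"
    rgbv <- grDevices::col2rgb(colhex)[, 1] / 255
    xs <- max(1L, floor(geometries$x0[i] * scale) + 1L):
          min(W, ceiling(geometries$x1[i] * scale))
    ys <- max(1L, floor(geometries$y0[i] * scale) + 1L):
          min(H, ceiling(geometries$y1[i] * scale))
    for (ch in 1:3) img[ys, xs, ch] <- rgbv[ch]
  }
  called <- calls[calls != "ungated"]
  fractions <- if (length(called)) {
    tb <- table(called)
    data.frame(class = names(tb), fraction = as.numeric(tb) / length(called),
               row.names = NULL)
  } else data.frame(class = character(0), fraction = numeric(0))
  if (!is.null(file)) png::writePNG(img, file)
  list(raster = img, fractions = fractions)
}
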