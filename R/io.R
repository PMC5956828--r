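#' @include AllClasses.R
NULL

#' Write and read the labelled reference set as CSV
#'
#' Columns: \code{tile_id,label,f0..f\{D-1\}}.
#'
#' @param reference a labelled [TileSet-class].
#' @param file CSV path.
#' @return \code{writeReferenceCSV}: the path, invisibly;
#'   \code{readReferenceCSV}: a [TileSet-class].
#' @export
writeReferenceCSV <- function(reference, file) {
  X <- tileFeatures(reference)
  df <- data.frame(tile_id = tileIds(reference),
                   label = unname(tileLabels(reference)),
                   X, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("f%d", seq_len(ncol(X)) - 1L)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeReferenceCSV
#' @export
readReferenceCSV <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  fcols <- grep("^f[0-9]+$", colnames(df))
  tileSet(as.matrix(df[, fcols]), df$tile_id, labels = df$label,
          slideId = "reference")
}

#' Write and read a slide as a directory
#'
#' A slide directory holds \code{tiles.csv} with columns
#' \code{tile_id,row,col,p_lesional,p_c0..p_c\{K-1\},f0..f\{D-1\}} and
#' \code{slide.json} with the truth metadata and class-name order.
#' Pre-computed provider outputs read this way feed the pipeline directly,
#' bypassing image decoding entirely.
#'
#' @param slide a [TileSet-class] with probability columns.
#' @param dir directory to create/read.
#' @return \code{writeSlideDir}: the directory, invisibly;
#'   \code{readSlideDir}: a [TileSet-class].
#' @export
writeSlideDir <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- tileFeatures(slide)
  P <- classProbs(slide)
  cd <- colData(slide)
  df <- data.frame(tile_id = cd$tile_id, row = cd$row, col = cd$col,
                   p_lesional = cd$p_lesional, P, X, check.names = FALSE)
  kp <- 4 + ncol(P)
  colnames(df)[5:kp] <- sprintf("p_c%d", seq_len(ncol(P)) - 1L)
  colnames(df)[(kp + 1):ncol(df)] <- sprintf("f%d", seq_len(ncol(X)) - 1L)
  utils::write.csv(df, file.path(dir, "tiles.csv"), row.names = FALSE)
  meta <- list(slide_id = slideId(slide),
               class_names = metadata(slide)$classNames,
               truth = slideTruth(slide))
  jsonlite::write_json(meta, file.path(dir, "slide.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSlideDir
#' @export
readSlideDir <- function(dir) {
  df <- utils::read.csv(file.path(dir, "tiles.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "slide.json"),
                              simplifyVector = TRUE)
  pcols <- grep("^p_c[0-9]+$", colnames(df))
  fcols <- grep("^f[0-9]+$", colnames(df))
  P <- as.matrix(df[, pcols])
  colnames(P) <- meta$class_names
  tileSet(as.matrix(df[, fcols]), df$tile_id, row = df$row, col = df$col,
          classProbs = P, pLesional = df$p_lesional,
          classNames = meta$class_names, slideId = meta$slide_id,
          truth = as.list(meta$truth))
}

#' Write the per-slide truth table as CSV
#'
#' Columns: \code{slide_id,truth_class,is_lesional,is_trained}.
#'
#' @param slides list of [TileSet-class] synthetic slides.
#' @param file CSV path.
#' @return the truth data.frame, invisibly.
#' @export
writeTruthCSV <- function(slides, file) {
  rows <- lapply(slides, function(s) {
    tr <- slideTruth(s)
    data.frame(slide_id = slideId(s), truth_class = tr$truthClass,
               is_lesional = isTRUE(tr$truthIsLesional),
               is_trained = isTRUE(tr$truthIsTrained))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
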