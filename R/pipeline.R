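#' @include AllClasses.R
NULL

#' Classify one slide against a labelled reference set
#'
#' Runs the complete per-slide workflow:
#' \enumerate{
#'   \item gate tiles by lesional probability (strictly greater than the
#'     configured threshold);
#'   \item sample uniformly down to the per-slide tile budget;
#'   \item stop with \code{INSUFFICIENT_LESIONAL} (plus a handful of review
#'     tiles) when fewer than the minimum number of gated tiles remain;
#'   \item re-embed reference and sampled query tiles jointly on the 2-D
#'     map;
#'   \item discretize each query tile by the k-nearest-neighbour purity
#'     rule (reference neighbours only) and tabulate the calls;
#'   \item render the statistical verdict by iterative chi-square testing;
#'   \item compute the softmax-averaging baseline, the combined
#'     (concordance) call and the hybrid blended score.
#' }
#' All stochastic steps derive their seed from \code{config@seed} and the
#' slide identifier, so repeated calls are byte-identical.
#'
#' @param slide a [TileSet-class] with probability columns (see
#'   [makeSlide()] or [readSlideDir()]).
#' @param reference a labelled [TileSet-class]; pass the output of
#'   [applyRefinement()] to classify against a refined map's retained
#'   points.
#' @param config a [PipelineConfig-class].
#' @param method embedding method, \code{"tsne"} (default) or \code{"pca"}.
#' @return A [SlideReport-class].
#' @export
classifySlide <- function(slide, reference, config = pipelineConfig(),
                          method = c("tsne", "pca")) {
  method <- match.arg(method)
  sid <- slideId(slide)
  if (is.null(sid) || is.na(sid)) sid <- "slide"
  seed <- derive_seed(config@seed, sid)

  nInput <- ncol(slide)
  gated <- gateLesional(slide, config@lesionalThreshold)
  sampled <- sampleTiles(gated, config@maxTilesPerSlide, seed)
  chk <- checkMinTiles(sampled, config@minLesionalTiles)

  counts <- c(input = nInput, gated = ncol(gated), sampled = ncol(sampled))
  emptyAssign <- DataFrame(tile_id = character(0), call = character(0),
                           purity = numeric(0))

  if (chk$status == "INSUFFICIENT_LESIONAL") {
    dec <- new("SlideDecision", status = "INSUFFICIENT_LESIONAL",
               classes = character(0),
               trail = data.frame(), alpha = config@alpha)
    return(new("SlideReport", slideId = sid, decision = dec,
               assignments = emptyAssign, contingency = numeric(0),
               tileFractions = numeric(0), outlierFraction = NA_real_,
               probMeans = numeric(0), probTop = NA_character_,
               combined = "UNDEFINED", hybrid = numeric(0),
               nTiles = counts, review = chk$review))
  }

  emb <- embedWithQueries(reference, sampled, method = method,
                          perplexity = config@perplexity, seed = seed)
  asg <- assignTiles(emb$query, emb$reference, emb$labels,
                     k = config@knnK, purity = config@knnPurity,
                     tileIds = tileIds(sampled))
  tab <- tabulateAssignments(asg)
  dec <- decideSlide(tab, alpha = config@alpha)

  classLevels <- sort(unique(emb$labels))
  classCalls <- asg$call[asg$call != OUTLIER_LABEL]
  frac <- stats::setNames(numeric(length(classLevels)), classLevels)
  if (length(classCalls)) {
    tb <- table(factor(classCalls, levels = classLevels))
    frac[] <- as.numeric(tb) / length(classCalls)
  }
  outFrac <- mean(asg$call == OUTLIER_LABEL)

  P <- classProbs(gated)
  pd <- probabilityDiagnosis(P)
  comb <- combinedDecision(dec, pd$top)
  ord <- names(pd$means)
  fr <- frac[ord]
  fr[is.na(fr)] <- 0
  names(fr) <- ord
  hyb <- hybridScores(fr, pd$means, config@hybridWeight)

  new("SlideReport", slideId = sid, decision = dec, assignments = asg,
      contingency = tab, tileFractions = frac, outlierFraction = outFrac,
      probMeans = pd$means, probTop = pd$top, combined = comb,
      hybrid = hyb, nTiles = counts, review = character(0))
}

#' Serialize a slide report to JSON
#'
#' Writes the verdict, the full chi-square trail, the contingency table and
#' the composite scores. Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report a [SlideReport-class].
#' @param file path of the JSON file; omit to return the JSON string.
#' @return the file path (or JSON string), invisibly.
#' @export
reportToJSON <- function(report, file = NULL) {
  dec <- report@decision
  obj <- list(
    slide_id = report@slideId,
    status = dec@status,
    classes = as.list(dec@classes),
    alpha = dec@alpha,
    trail = dec@trail,
    n_tiles = as.list(report@nTiles),
    contingency = as.list(report@contingency),
    tile_fractions = as.list(report@tileFractions),
    outlier_fraction = report@outlierFraction,
    prob_means = as.list(report@probMeans),
    prob_top = report@probTop,
    combined = report@combined,
    hybrid = as.list(report@hybrid),
    review_tiles = as.list(report@review),
    assignments = as.data.frame(report@assignments)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(file)) return(invisible(as.character(js)))
  writeLines(js, file)
  invisible(file)
}

#' Serialize and read pipeline configurations
#'
#' @param config a [PipelineConfig-class].
#' @param file JSON path.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, file) {
  slots <- slotNames("PipelineConfig")
  obj <- stats::setNames(lapply(slots, function(s) slot(config, s)), slots)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(pipelineConfig, obj)
}
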