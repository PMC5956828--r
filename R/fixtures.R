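#' @include AllClasses.R
NULL

#' Place class means in feature space
#'
#' Class means are drawn as seeded random directions scaled to radius
#' \code{classSeparation * withinClassSd} and accepted only when every
#' pairwise distance reaches that same radius, so the configuration is a
#' reproducible function of the seed. Means therefore lie on a common sphere
#' whose centre (the origin) is an "unoccupied" interior region exactly one
#' separation away from every class -- the region where novel-class clusters
#' are planted by [makeNovelSlide()].
#'
#' @param config a [FixtureConfig-class].
#' @param maxTries rejection-sampling attempts before giving up.
#' @return numeric matrix (nClasses x featureDim) with classes as rownames.
#' @export
placeClassMeans <- function(config, maxTries = 500L) {
  K <- config@nClasses
  D <- config@featureDim
  R <- config@classSeparation * config@withinClassSd
  with_seed(config@seed, {
    for (i in seq_len(maxTries)) {
      M <- matrix(stats::rnorm(K * D), K, D)
      M <- M / sqrt(rowSums(M * M)) * R
      if (min(stats::dist(M)) >= R) {
        rownames(M) <- config@classNames
        return(M)
      }
    }
    stop("could not place ", K, " class means at pairwise distance >= ",
         R, " in ", D, " dimensions; featureDim is too small for the ",
         "requested classSeparation")
  })
}

#' Generate the labelled synthetic reference set
#'
#' Draws, for each class, a tile count uniformly from
#' \code{tilesPerClassRange} and that many feature vectors from an isotropic
#' Gaussian at the class mean. Output is fully determined by the
#' configuration seed: two calls with the same config are identical.
#'
#' @param config a [FixtureConfig-class].
#' @return A [TileSet-class] with a \code{label} column.
#' @examples
#' cfg <- fixtureConfig(nClasses = 3, featureDim = 32,
#'                      tilesPerClassRange = c(10, 10), seed = 7)
#' ref <- makeReferenceSet(cfg)
#' table(tileLabels(ref))
#' @export
makeReferenceSet <- function(config) {
  M <- placeClassMeans(config)
  K <- config@nClasses
  D <- config@featureDim
  sd <- config@withinClassSd
  r <- config@tilesPerClassRange
  with_seed(config@seed + 1L, {
    counts <- if (r[1] == r[2]) rep(r[1], K) else
      sample(seq.int(r[1], r[2]), K, replace = TRUE)
    feats <- vector("list", K)
    labs <- vector("list", K)
    ids <- vector("list", K)
    for (c in seq_len(K)) {
      n <- counts[c]
      feats[[c]] <- sweep(matrix(stats::rnorm(n * D, sd = sd), n, D),
                          2, M[c, ], "+")
      labs[[c]] <- rep(config@classNames[c], n)
      ids[[c]] <- sprintf("ref_%s_%04d", config@classNames[c], seq_len(n))
    }
    tileSet(do.call(rbind, feats), unlist(ids), labels = unlist(labs),
            classNames = config@classNames, slideId = "reference",
            truth = list())
  })
}

## Shared tile assembly: features -> mock probabilities, lesional score,
## grid positions, TileSet.
.assemble_slide <- function(features, config, means, slideId, truth) {
  n <- nrow(features)
  P <- t(apply(features, 1, softmax_class_probs, means = means,
               temperature = config@softmaxTemperature))
  colnames(P) <- config@classNames
  pl <- rowSums(P[, config@lesionClassIds, drop = FALSE])
  ncols <- max(1L, ceiling(sqrt(n)))
  tileSet(features,
          tileIds = sprintf("%s_t%04d", slideId, seq_len(n)),
          row = (seq_len(n) - 1L) %/% ncols,
          col = (seq_len(n) - 1L) %% ncols,
          classProbs = P, pLesional = pl,
          classNames = config@classNames, slideId = slideId, truth = truth)
}

#' Generate a synthetic slide of a trained class
#'
#' Emulates the tile set of one whole-slide image: \code{nLesional} tiles
#' from the cluster of the (lesional) truth class, plus \code{nBackground}
#' contaminating tiles drawn from the non-lesional class clusters. Each
#' tile's class-probability vector is the squared-distance softmax against
#' all trained class means and its lesional probability the summed mass of
#' the lesion classes, mimicking the two-model (lesion gate + classifier)
#' CNN readout.
#'
#' @param config a [FixtureConfig-class].
#' @param truthClass class name or index of the slide's true class.
#' @param nLesional number of truth-class tiles.
#' @param nBackground number of non-lesional contaminating tiles.
#' @param seed integer seed for this slide.
#' @param slideId optional identifier.
#' @return A [TileSet-class] with probability columns and truth metadata.
#' @export
makeSlide <- function(config, truthClass, nLesional, nBackground = 0L,
                      seed = config@seed, slideId = NULL) {
  M <- placeClassMeans(config)
  if (is.numeric(truthClass)) truthClass <- config@classNames[truthClass]
  if (!truthClass %in% config@classNames)
    stop("unknown truthClass: ", truthClass)
  if (nLesional < 0 || nBackground < 0) stop("tile counts must be >= 0")
  if (nLesional + nBackground == 0L)
    stop("empty slide: nLesional and nBackground are both 0")
  ci <- match(truthClass, config@classNames)
  D <- config@featureDim
  sd <- config@withinClassSd
  bg_ids <- setdiff(seq_len(config@nClasses), config@lesionClassIds)
  if (nBackground > 0L && length(bg_ids) == 0L)
    stop("no non-lesional classes to draw background tiles from")
  if (is.null(slideId)) slideId <- sprintf("slide_%s_s%d", truthClass, seed)
  with_seed(seed, {
    les <- sweep(matrix(stats::rnorm(nLesional * D, sd = sd), nLesional, D),
                 2, M[ci, ], "+")
    bg <- NULL
    if (nBackground > 0L) {
      bc <- sample(bg_ids, nBackground, replace = TRUE)
      bg <- M[bc, , drop = FALSE] +
        matrix(stats::rnorm(nBackground * D, sd = sd), nBackground, D)
    }
    .assemble_slide(rbind(les, bg), config, M, slideId,
                    truth = list(truthClass = truthClass,
                                 truthIsLesional = ci %in% config@lesionClassIds,
                                 truthIsTrained = TRUE))
  })
}

#' Generate a synthetic slide of a novel (untrained) class
#'
#' Emulates a tumour type the mock CNN has never seen. A new cluster mean is
#' planted in the unoccupied interior of feature space: the closest
#' admissible point to the origin of the class-mean sphere along a seeded
#' random direction, subject to being at least
#' \code{offsetSd * withinClassSd} away from every trained mean. Probability
#' vectors are still computed against the trained means -- the mock network
#' knows nothing of the novel class -- so such tiles typically carry
#' confident (and wrong) softmax scores, the hallmark of closed-set
#' classifiers confronted with open-set inputs.
#'
#' @param config a [FixtureConfig-class].
#' @param offsetSd minimum distance of the novel mean from every trained
#'   mean, in within-class SD units.
#' @param nTiles number of tiles to draw.
#' @param seed integer seed for this slide.
#' @param slideId optional identifier.
#' @return A [TileSet-class] with \code{truthClass = "NOVEL"} metadata.
#' @export
makeNovelSlide <- function(config, offsetSd = 10, nTiles = 100L,
                           seed = config@seed, slideId = NULL) {
  if (offsetSd <= 0) stop("offsetSd must be > 0")
  if (nTiles < 1L) stop("nTiles must be >= 1")
  M <- placeClassMeans(config)
  D <- config@featureDim
  sd <- config@withinClassSd
  off <- offsetSd * sd
  if (is.null(slideId)) slideId <- sprintf("slide_novel_s%d", seed)
  with_seed(seed, {
    u <- stats::rnorm(D)
    u <- u / sqrt(sum(u * u))
    ## walk outward along u from the origin until the offset constraint
    ## holds; t = 0 already satisfies it when offsetSd <= classSeparation
    tmax <- config@classSeparation * sd + off + 1
    t <- 0
    nm <- NULL
    while (t <= tmax) {
      cand <- t * u
      if (min(sqrt(sqdist_to(cand, M))) >= off) { nm <- cand; break }
      t <- t + 0.05 * sd
    }
    if (is.null(nm))
      stop("could not place a novel mean at distance >= ", off,
           " from every trained class mean in ", D, " dimensions")
    feats <- sweep(matrix(stats::rnorm(nTiles * D, sd = sd), nTiles, D),
                   2, nm, "+")
    .assemble_slide(feats, config, M, slideId,
                    truth = list(truthClass = "NOVEL",
                                 truthIsLesional = TRUE,
                                 truthIsTrained = FALSE))
  })
}
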