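test_that("reference set respects per-class counts and is seed-deterministic", {
  cfg <- fixtureConfig(nClasses = 3, featureDim = 32,
                       tilesPerClassRange = c(10, 10), seed = 7)
  ref <- makeReferenceSet(cfg)
  expect_equal(ncol(ref), 30L)
  expect_equal(unname(table(tileLabels(ref))), rep(10L, 3),
               ignore_attr = TRUE)

  ref2 <- makeReferenceSet(cfg)
  expect_identical(tileFeatures(ref), tileFeatures(ref2))
  expect_identical(tileIds(ref), tileIds(ref2))

  cfgv <- fixtureConfig(nClasses = 4, featureDim = 32,
                        tilesPerClassRange = c(8, 20), seed = 3)
  counts <- table(tileLabels(makeReferenceSet(cfgv)))
  expect_true(all(counts >= 8 & counts <= 20))
})

test_that("class means honour the separation constraint or fail loudly", {
  cfg <- tiny_config()
  M <- placeClassMeans(cfg)
  expect_gte(min(dist(M)), cfg@classSeparation * cfg@withinClassSd)

  # 13 means at mutual distance >= radius cannot fit on a circle in 2-D
  cramped <- fixtureConfig(nClasses = 13, featureDim = 2, seed = 1)
  expect_error(placeClassMeans(cramped), "featureDim")
})

test_that("nearest-class-mean classification of generated tiles is near-perfect", {
  # the separation property: with 10-sd spacing the clusters are linearly
  # separable regardless of dimensionality
  for (D in c(32L, 1024L)) {
    cfg <- fixtureConfig(nClasses = 6, featureDim = D,
                         tilesPerClassRange = c(20, 20),
                         lesionClassIds = 1:3, seed = 11)
    M <- placeClassMeans(cfg)
    n <- 1000L
    cls <- withr::with_seed(1, sample(6, n, replace = TRUE))
    X <- M[cls, ] + withr::with_seed(2, matrix(rnorm(n * D), n, D))
    pred <- apply(X, 1, function(x)
      which.min(colSums((t(M) - x)^2)))
    expect_gte(mean(pred == cls), 0.99)
  }
})

test_that("slide probability vectors are normalized softmax scores", {
  cfg <- tiny_config()
  sl <- makeSlide(cfg, 1, nLesional = 40, nBackground = 10, seed = 5)
  expect_equal(ncol(sl), 50L)
  P <- classProbs(sl)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  pl <- pLesional(sl)
  expect_true(all(pl >= 0 & pl <= 1))
  # lesional probability is exactly the lesion-class mass
  expect_equal(unname(pl),
               unname(rowSums(P[, cfg@lesionClassIds, drop = FALSE])))
})

test_that("mock probabilities reflect cluster geometry", {
  cfg <- tiny_config()
  prov <- mockProvider(cfg)
  M <- placeClassMeans(cfg)
  # a tile exactly at a class mean is called with near certainty: the
  # nearest other mean is >= 10 sd away so its softmax weight is ~exp(-50)
  p <- classProbs(prov, M[2, ])
  expect_equal(unname(which.max(p)), 2L)
  expect_gt(max(p), 0.99)
  # a tile exactly equidistant from all means scores uniformly: three means
  # on orthogonal axes are equidistant from the origin, so every softmax
  # weight ties and the vector collapses to 1/K
  cfg3 <- fixtureConfig(nClasses = 3, featureDim = 3, lesionClassIds = 1,
                        seed = 1)
  prov3 <- new("MockEmbeddingProvider", classMeans = diag(3) * 10,
               classNames = cfg3@classNames, lesionClassIds = 1L,
               temperature = 1)
  expect_equal(unname(classProbs(prov3, c(0, 0, 0))), rep(1 / 3, 3))
})

test_that("novel slides sit at the required offset and are marked untrained", {
  cfg <- tiny_config()
  M <- placeClassMeans(cfg)
  nv <- makeNovelSlide(cfg, offsetSd = 10, nTiles = 25, seed = 9)
  tr <- slideTruth(nv)
  expect_false(tr$truthIsTrained)
  expect_identical(tr$truthClass, "NOVEL")
  # recover the cluster mean from the tiles and check the offset
  ctr <- colMeans(tileFeatures(nv))
  dmin <- min(sqrt(colSums((t(M) - ctr)^2)))
  expect_gte(dmin, 10 * cfg@withinClassSd - 1.5)  # 1.5: mean-estimate noise
  # probabilities still normalized even though the class is unknown
  expect_true(all(abs(rowSums(classProbs(nv)) - 1) < 1e-9))

  expect_error(makeNovelSlide(cfg, offsetSd = 0, nTiles = 5), "offsetSd")
})

test_that("empty and invalid slide requests are rejected", {
  cfg <- tiny_config()
  expect_error(makeSlide(cfg, 1, 0, 0), "empty slide")
  expect_error(makeSlide(cfg, "not_a_class", 10), "unknown truthClass")
  expect_error(fixtureConfig(tilesPerClassRange = c(10, 5)), "tilesPerClassRange")
  expect_error(fixtureConfig(lesionClassIds = integer(0)), "lesionClassIds")
})

test_that("reference CSV and slide directory round-trips preserve content", {
  cfg <- tiny_config(npc = 8L)
  ref <- makeReferenceSet(cfg)
  f <- tempfile(fileext = ".csv")
  writeReferenceCSV(ref, f)
  ref2 <- readReferenceCSV(f)
  expect_equal(tileFeatures(ref2), tileFeatures(ref), tolerance = 1e-12)
  expect_identical(unname(tileLabels(ref2)), unname(tileLabels(ref)))

  sl <- makeSlide(cfg, 2, 12, 3, seed = 4)
  d <- tempfile()
  writeSlideDir(sl, d)
  sl2 <- readSlideDir(d)
  expect_equal(classProbs(sl2), classProbs(sl), tolerance = 1e-12)
  expect_identical(slideTruth(sl2)$truthClass, slideTruth(sl)$truthClass)
})
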