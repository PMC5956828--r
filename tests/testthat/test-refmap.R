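# Small fixtures keep the embedding tests fast; cluster geometry still has
# 10-sd separation so neighbourhood structure is unambiguous.

test_that("PCA maps are exact, deterministic projections", {
  # three collinear points in feature space stay collinear on the plane:
  # the second component carries (numerically) zero variance
  X <- rbind(c(0, 0, 0, 0), c(1, 2, 0, 0), c(2, 4, 0, 0))
  m <- buildReferenceMap(X, labels = c("a", "b", "a"), method = "pca")
  expect_equal(nrow(mapCoords(m)), 3L)
  expect_lt(stats::var(mapCoords(m)[, 2]), 1e-20)

  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  m1 <- buildReferenceMap(ref, method = "pca")
  m2 <- buildReferenceMap(ref, method = "pca")
  expect_identical(mapCoords(m1), mapCoords(m2))
  # projecting the training features onto the stored components reproduces
  # the map exactly
  proj <- sweep(tileFeatures(ref), 2, m1@pca$center) %*% m1@pca$rotation
  expect_equal(unname(proj), mapCoords(m1), tolerance = 1e-12)
})

test_that("t-SNE maps conserve points, respect the seed, and separate classes", {
  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  m <- buildReferenceMap(ref, perplexity = 10, seed = 4)
  expect_equal(nrow(mapCoords(m)), ncol(ref))
  expect_true(all(is.finite(mapCoords(m))))

  m2 <- buildReferenceMap(ref, perplexity = 10, seed = 4)
  expect_identical(mapCoords(m), mapCoords(m2))
  expect_false(identical(mapCoords(buildReferenceMap(ref, perplexity = 10,
                                                     seed = 5)),
                         mapCoords(m)))

  # well-separated clusters give high own-class purity among each point's
  # 25 nearest map neighbours
  co <- mapCoords(m)
  labs <- mapLabels(m)
  pur <- vapply(seq_len(nrow(co)), function(i) {
    d2 <- colSums((t(co) - co[i, ])^2)
    d2[i] <- Inf
    mean(labs[order(d2)[1:25]] == labs[i])
  }, numeric(1))
  expect_gte(mean(pur), 0.9)

  expect_error(buildReferenceMap(ref, perplexity = 200, seed = 1),
               "perplexity")
  expect_error(buildReferenceMap(tileFeatures(ref)), "labels")
})

test_that("map refinement removes planted mislabels and is idempotent", {
  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  # plant a mislabelled tile: features of class 2, labelled as class 1
  M <- placeClassMeans(cfg)
  bad <- tileSet(rbind(tileFeatures(ref), M[2, ]),
                 c(tileIds(ref), "planted_mislabel"),
                 labels = c(unname(tileLabels(ref)), cfg@classNames[1]))
  m <- buildReferenceMap(bad, perplexity = 10, seed = 2)
  r <- refineReferenceMap(m, nCheckNeighbors = 30, ownClassMin = 0.5)
  expect_false("planted_mislabel" %in% r@tileIds)
  # clean points survive: at most the planted point is removed
  expect_gte(nrow(mapCoords(r)), ncol(ref))

  # idempotent on its own output
  r2 <- refineReferenceMap(r, nCheckNeighbors = 30, ownClassMin = 0.5)
  expect_identical(r2@tileIds, r@tileIds)

  # ownClassMin = 0 is the identity
  r0 <- refineReferenceMap(m, nCheckNeighbors = 30, ownClassMin = 0)
  expect_identical(r0@tileIds, m@tileIds)

  expect_error(refineReferenceMap(m, nCheckNeighbors = 10000), "points")

  # refinement must not empty a class
  few <- tileSet(rbind(matrix(rnorm(40 * 4), 40, 4),
                       matrix(rnorm(4) + 20, 1, 4)),
                 sprintf("t%02d", 1:41),
                 labels = c(rep("a", 40), "b"))
  mf <- buildReferenceMap(few, method = "pca")
  expect_error(refineReferenceMap(mf, nCheckNeighbors = 20, ownClassMin = 0.5),
               "class")
})

test_that("refinement bookkeeping propagates to the reference tile set", {
  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  m <- buildReferenceMap(ref, perplexity = 10, seed = 2)
  r <- refineReferenceMap(m, nCheckNeighbors = 30, ownClassMin = 0.5)
  expect_true(r@refined)
  expect_equal(sum(r@provenance$after), nrow(mapCoords(r)))
  sub <- applyRefinement(ref, r)
  expect_setequal(tileIds(sub), r@tileIds)
})

test_that("joint re-embedding carries queries without disturbing the map", {
  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  sl <- makeSlide(cfg, 1, 30, 0, seed = 6)
  q <- tileFeatures(sl)

  emb <- embedWithQueries(ref, q, perplexity = 10, seed = 3)
  expect_equal(nrow(emb$reference) + nrow(emb$query), ncol(ref) + nrow(q))
  expect_equal(length(emb$labels), ncol(ref))

  # determinism under the seed
  emb2 <- embedWithQueries(ref, q, perplexity = 10, seed = 3)
  expect_identical(emb$query, emb2$query)

  # queries from a trained cluster acquire pure neighbourhoods
  asg <- assignTiles(emb$query, emb$reference, emb$labels, k = 25,
                     purity = 0.85)
  expect_gte(mean(asg$call == cfg@classNames[1]), 0.85)

  # reference purity is stable against the addition of queries
  pur <- function(co, labs) mean(vapply(seq_len(nrow(co)), function(i) {
    d2 <- colSums((t(co) - co[i, ])^2)
    d2[i] <- Inf
    mean(labs[order(d2)[1:25]] == labs[i])
  }, numeric(1)))
  solo <- buildReferenceMap(ref, perplexity = 10, seed = 3)
  p_before <- pur(mapCoords(solo), mapLabels(solo))
  p_after <- pur(emb$reference, emb$labels)
  expect_lte(abs(p_before - p_after), 0.05)

  expect_error(embedWithQueries(ref, q[, 1:10], perplexity = 10), "mismatch")
  expect_error(embedWithQueries(ref, q[0, , drop = FALSE]), "empty")
})

test_that("reference maps serialize to JSON and back", {
  cfg <- tiny_config(npc = 15L)
  ref <- makeReferenceSet(cfg)
  m <- buildReferenceMap(ref, method = "pca")
  f <- tempfile(fileext = ".json")
  writeReferenceMap(m, f)
  m2 <- readReferenceMap(f)
  expect_equal(mapCoords(m2), mapCoords(m), tolerance = 1e-12)
  expect_identical(mapLabels(m2), mapLabels(m))
  expect_identical(mapMethod(m2), "pca")
})
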