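test_that("one-vs-rest AUC handles perfect, random and worked cases", {
  # perfectly separating scores
  S <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  colnames(S) <- c("A", "B")
  truth <- c("A", "A", "B", "B")
  expect_equal(mrocAuc(S, truth)$macro, 1.0)

  # a constant discriminant is chance level
  S0 <- matrix(0.5, 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(mrocAuc(S0, truth)$perClass), c(0.5, 0.5))

  # worked 4-slide set: A-scores 0.9/0.6 for true A, 0.4/0.2 for true B
  S1 <- cbind(A = c(0.9, 0.6, 0.4, 0.2), B = c(0.1, 0.4, 0.6, 0.8))
  expect_equal(mrocAuc(S1, truth)$perClass[["A"]], 1.0)
  # swapping one pair (0.6 <-> 0.4) leaves 3 of 4 discordant-free pairs
  S2 <- cbind(A = c(0.9, 0.4, 0.6, 0.2), B = c(0.1, 0.6, 0.4, 0.8))
  expect_equal(mrocAuc(S2, truth)$perClass[["A"]], 0.75)

  expect_error(mrocAuc(S, rep("A", 4)), "distinct truth classes")
})

test_that("trapezoidal AUC equals pair counting on random instances", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    k <- sample(2:4, 1)
    truth <- sample(LETTERS[1:k], n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    S <- matrix(round(runif(n * k), 2), n, k,
                dimnames = list(NULL, LETTERS[1:k]))
    got <- mrocAuc(S, truth)
    for (cl in names(got$perClass)) {
      expect_equal(got$perClass[[cl]], oracle_auc(S[, cl], truth == cl),
                   tolerance = 1e-12)
    }
  }
})

test_that("trapezoidal AUC agrees with the pROC reference implementation", {
  set.seed(23)
  score <- runif(40)
  pos <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  S <- cbind(A = score, B = 1 - score)
  truth <- ifelse(pos, "A", "B")
  got <- mrocAuc(S, truth)$perClass[["A"]]
  want <- as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cutoff sweeps exclude low-confidence slides and shrink coverage", {
  pred <- c("A", "A", "B", "B", NA)
  score <- c(0.9, 0.6, 0.55, 0.95, NA)
  truth <- c("A", "B", "B", "B", "A")
  sw <- accuracySweep(pred, score, truth, cutoffs = c(0, 0.7, 0.99),
                      mode = "PROB_TOP_SCORE")
  # cutoff 0: all predicted slides count
  expect_equal(sw$coverage[1], 4 / 5)
  expect_equal(sw$accuracy[1], 3 / 4)
  # cutoff 0.7: the 0.55 and 0.6 slides drop out
  expect_equal(sw$coverage[2], 2 / 5)
  expect_equal(sw$accuracy[2], 1)
  # cutoff above every score: nothing classified, accuracy absent
  expect_equal(sw$coverage[3], 0)
  expect_true(is.na(sw$accuracy[3]))
  # coverage is non-increasing in the cutoff
  expect_true(all(diff(sw$coverage) <= 0))

  expect_error(accuracySweep(pred, score, truth, cutoffs = numeric(0)),
               "empty")
})

test_that("error typing implements the A/B/C taxonomy", {
  lesions <- c("glioma", "meningioma", "schwannoma", "metastasis", "lymphoma")
  trained <- c(lesions, "grey_matter", "dura")
  te <- function(p, tc, il, it) typeErrors(p, tc, il, it, lesions, trained)

  # normal tissue called a lesion
  expect_equal(te("glioma", "grey_matter", FALSE, TRUE), "TYPE_A")
  # wrong lesion class for a trained lesion
  expect_equal(te("metastasis", "meningioma", TRUE, TRUE), "TYPE_B")
  # untrained truth called as any trained class
  expect_equal(te("glioma", "NOVEL", TRUE, FALSE), "TYPE_C")
  # uncertainty verdicts are excluded from scoring
  expect_equal(te(NA, "glioma", TRUE, TRUE), "EXCLUDED")
  expect_equal(te("UNDEFINED", "glioma", TRUE, TRUE), "EXCLUDED")
  expect_equal(te("meningioma", "meningioma", TRUE, TRUE), "CORRECT")
  expect_error(te("glioma", "astrocytoma?", TRUE, TRUE), "unknown truth")
})

test_that("cohort evaluation partitions every slide exactly once", {
  cfg <- tiny_config()
  ref <- makeReferenceSet(cfg)
  pc <- pipelineConfig(perplexity = 10, minLesionalTiles = 5L, seed = 2)
  slides <- c(
    lapply(1:4, function(i) makeSlide(cfg, (i %% 2) + 1, 25, 5, seed = i)),
    list(makeNovelSlide(cfg, 10, 25, seed = 90)))
  reports <- lapply(slides, classifySlide, reference = ref, config = pc)
  truth <- writeTruthCSV(slides, tempfile(fileext = ".csv"))
  ev <- evaluateSlides(reports, truth,
                       lesionClasses = cfg@classNames[cfg@lesionClassIds])
  ps <- ev@perSlide
  for (m in unique(ps$method)) {
    rows <- ps[ps$method == m, ]
    expect_equal(nrow(rows), length(slides))
    expect_true(all(rows$outcome %in%
      c("CORRECT", "TYPE_A", "TYPE_B", "TYPE_C", "EXCLUDED")))
  }
  # sweep curves inherit the coverage monotonicity
  for (sw in ev@sweeps) expect_true(all(diff(sw$coverage) <= 1e-12))

  d <- tempfile()
  writeEvaluation(ev, d)
  expect_true(file.exists(file.path(d, "per_slide.csv")))
  expect_true(file.exists(file.path(d, "sweep_prob_top_score.csv")))
})
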