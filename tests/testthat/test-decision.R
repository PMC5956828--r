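test_that("chi-square closed forms are exact", {
  t1 <- chi2Uniform(c(50, 50))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$df, 1L)
  expect_equal(t1$p.value, 1)

  # at df = 2 the survival function is exp(-x/2), an analytic identity
  t2 <- chi2Uniform(c(40, 35, 25))
  expect_equal(t2$statistic, 3.5)
  expect_equal(t2$df, 2L)
  expect_equal(t2$p.value, exp(-1.75))

  t3 <- chi2Uniform(c(90, 5, 5))
  expect_equal(t3$statistic, 144.5)
  expect_lt(t3$p.value, 1e-30)

  # single category: non-informative by convention
  expect_equal(chi2Uniform(42), list(statistic = 0, df = 0L, p.value = 1))

  expect_error(chi2Uniform(c(-1, 5)), "non-negative")
  expect_error(chi2Uniform(c(1.5, 2.5)), "integers")
  expect_error(chi2Uniform(numeric(0)), "at least one")
})

test_that("chi-square matches the stats implementation on random tables", {
  set.seed(2)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    x <- as.numeric(rmultinom(1, sample(10:200, 1), rep(1 / k, k)))
    if (any(x == 0)) next
    got <- chi2Uniform(x)
    want <- suppressWarnings(chisq.test(x, p = rep(1 / k, k)))
    expect_equal(got$statistic, unname(want$statistic))
    expect_equal(got$p.value, unname(want$p.value))
  }
})

test_that("iterative elimination renders the documented verdicts", {
  # dominant class: eliminate up to a singleton diagnosis
  d <- decideSlide(c(glioma = 90, meningioma = 5, lymphoma = 5))
  expect_equal(decisionStatus(d), "DIAGNOSIS")
  expect_equal(decisionClasses(d), "glioma")
  tr <- decisionTrail(d)
  # lymphoma drops first (count tie broken by label order), then meningioma
  expect_equal(tr$removed[tr$iteration == 1], "lymphoma")
  expect_equal(tr$removed[tr$iteration == 2], "meningioma")
  expect_equal(tr$statistic[tr$iteration == 2], 2 * 42.5^2 / 47.5)

  # flat distribution: differential of all three, count-descending
  d2 <- decideSlide(c(A = 40, B = 35, C = 25))
  expect_equal(decisionStatus(d2), "DIFFERENTIAL")
  expect_equal(decisionClasses(d2), c("A", "B", "C"))
  expect_equal(decisionTrail(d2)$p.value[2], exp(-1.75))

  # outlier-dominated slide: undefined on the first iteration
  tb3 <- c(OUTLIER = 60, glioma = 20, meningioma = 20)
  d3 <- decideSlide(tb3)
  expect_equal(decisionStatus(d3), "UNDEFINED")
  expect_equal(decisionTrail(d3)$statistic[1], 32)
  expect_lt(decisionTrail(d3)$p.value[1], 1e-6)

  # singleton table: immediate diagnosis
  d4 <- decideSlide(c(glioma = 100))
  expect_equal(decisionStatus(d4), "DIAGNOSIS")

  # outliers only, too few to be significant: still undefined (nothing
  # diagnosable remains once outliers are set aside)
  d5 <- decideSlide(c(OUTLIER = 30))
  expect_equal(decisionStatus(d5), "UNDEFINED")

  expect_error(decideSlide(numeric(0)), "empty")
  expect_error(decideSlide(c(10, 20)), "named")
})

test_that("differential diagnoses never contain the outlier category", {
  d <- decideSlide(c(OUTLIER = 30, A = 35, B = 35))
  expect_equal(decisionStatus(d), "DIFFERENTIAL")
  expect_false(OUTLIER_LABEL %in% decisionClasses(d))
  expect_setequal(decisionClasses(d), c("A", "B"))
})

test_that("elimination terminates and is monotone in alpha", {
  set.seed(8)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    tb <- setNames(as.numeric(rmultinom(1, sample(15:100, 1),
                                        runif(k, 0.2, 1))), letters[1:k])
    tb <- tb[tb > 0]
    if (!length(tb)) next
    d <- decideSlide(tb, alpha = 0.01)
    # halts within k iterations of elimination
    expect_lte(nrow(decisionTrail(d)), length(tb) + 1L)
    # a smaller alpha stops the elimination earlier (or at the same point),
    # so its retained class set contains the stricter one
    d_lo <- decideSlide(tb, alpha = 0.001)
    expect_true(all(decisionClasses(d) %in% decisionClasses(d_lo)))
  }
})

test_that("decision matches the brute-force oracle on random tables", {
  set.seed(31)
  for (i in 1:300) {
    k <- sample(1:4, 1)
    tb <- setNames(sample(1:30, k, replace = TRUE), LETTERS[1:k])
    if (runif(1) < 0.5) tb <- c(tb, OUTLIER = sample(0:30, 1))
    tb <- tb[tb > 0]
    if (!length(tb)) next
    got <- decideSlide(tb)
    want <- oracle_decide(tb)
    expect_identical(decisionStatus(got), want$status)
    expect_identical(decisionClasses(got), want$classes)
  }
})

test_that("probability baseline averages and ranks softmax scores", {
  P <- rbind(c(0.7, 0.3), c(0.9, 0.1))
  colnames(P) <- c("glioma", "meningioma")
  pd <- probabilityDiagnosis(P)
  expect_equal(unname(pd$means), c(0.8, 0.2))
  expect_equal(pd$top, "glioma")

  # identical rows reproduce the row
  P2 <- matrix(rep(c(0.25, 0.75), each = 4), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(probabilityDiagnosis(P2)$means), c(0.25, 0.75))

  # exact tie goes to the first class in order
  P3 <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(probabilityDiagnosis(P3)$top, "a")

  expect_error(probabilityDiagnosis(P[0, , drop = FALSE]), "no gated tiles")
})

test_that("composite rules combine the two classifiers as documented", {
  dx <- function(cl) new("SlideDecision", status = "DIAGNOSIS", classes = cl,
                         trail = data.frame(), alpha = 0.01)
  diff2 <- new("SlideDecision", status = "DIFFERENTIAL",
               classes = c("glioma", "meningioma"), trail = data.frame(),
               alpha = 0.01)
  expect_equal(combinedDecision(dx("glioma"), "glioma"), "glioma")
  expect_equal(combinedDecision(dx("glioma"), "meningioma"), "UNDEFINED")
  expect_equal(combinedDecision(diff2, "glioma"), "UNDEFINED")

  fr <- c(a = 0.8, b = 0.2, c = 0)
  pm <- c(a = 0.6, b = 0.3, c = 0.1)
  expect_equal(unname(hybridScores(fr, pm, 0.5)), c(0.7, 0.25, 0.05))
  expect_equal(hybridScores(fr, pm, 1), fr)
  expect_equal(hybridScores(fr, pm, 0), pm)
  expect_error(hybridScores(fr[1:2], pm), "length")
  expect_error(hybridScores(fr, pm, w = 1.5), "w must be")
})
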