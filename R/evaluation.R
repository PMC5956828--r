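#' @include AllClasses.R
NULL

## Trapezoidal one-vs-rest AUC for one class: scores for every slide,
## binary truth. Ties form plateaus; the trapezoid over a plateau equals
## the midrank convention of the Mann-Whitney statistic.
.ovr_auc <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  nP <- sum(positive)
  nN <- sum(!positive)
  tpr <- c(0, vapply(thr, function(t) sum(score[positive] >= t), 0) / nP)
  fpr <- c(0, vapply(thr, function(t) sum(score[!positive] >= t), 0) / nN)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Macro-averaged multiclass ROC AUC
#'
#' Approximates the multiclass ROC by one-vs-rest decomposition: for every
#' class present in the truth, the class's own score column is used as the
#' discriminant, the ROC curve is integrated by the trapezoidal rule
#' (midrank tie handling), and the per-class AUCs are macro-averaged.
#' Classes absent from the truth are skipped.
#'
#' @param scores slides x classes score matrix (tile fractions, mean
#'   probabilities, or hybrid scores); column names are class labels.
#' @param truth true class per slide (restricted to trained-class slides).
#' @return list with \code{macro} (the macro-average) and \code{perClass}
#'   (named per-class AUCs).
#' @export
mrocAuc <- function(scores, truth) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(truth))
  present <- intersect(colnames(scores), unique(truth))
  if (length(unique(truth)) < 2L)
    stop("need at least 2 distinct truth classes for ROC analysis")
  per <- vapply(present, function(cl) {
    .ovr_auc(scores[, cl], truth == cl)
  }, numeric(1))
  list(macro = mean(per), perClass = per)
}

#' Accuracy/coverage sweep over confidence cutoffs
#'
#' Re-scores a cohort of slide predictions at a grid of minimum-confidence
#' cutoffs. A slide is classified at a cutoff when its confidence score
#' reaches the cutoff and a single-class prediction exists; all other
#' slides are deemed undefined and excluded from the accuracy at that
#' cutoff. The confidence score depends on the mode:
#' \describe{
#'   \item{\code{PROB_TOP_SCORE}}{the top mean softmax probability;}
#'   \item{\code{TSNE_OUTLIER_FRACTION}}{the fraction of sampled tiles
#'     falling in defined (non-outlier) space, i.e. one minus the outlier
#'     fraction, so that raising the cutoff is uniformly stricter in both
#'     modes.}
#' }
#'
#' @param predictions character vector of single-class predictions
#'   (\code{NA} for slides with an uncertainty verdict).
#' @param scores per-slide confidence score as defined above.
#' @param truth true class per slide.
#' @param cutoffs numeric cutoff grid.
#' @param mode \code{"PROB_TOP_SCORE"} or \code{"TSNE_OUTLIER_FRACTION"}
#'   (label only; the score must already match the mode).
#' @return data.frame \code{cutoff}, \code{accuracy}, \code{error},
#'   \code{coverage} (accuracy/error are \code{NA} where no slide is
#'   classified).
#' @export
accuracySweep <- function(predictions, scores, truth,
                          cutoffs = seq(0, 1, by = 0.05),
                          mode = c("PROB_TOP_SCORE", "TSNE_OUTLIER_FRACTION")) {
  mode <- match.arg(mode)
  if (length(cutoffs) == 0L) stop("cutoff grid is empty")
  stopifnot(length(predictions) == length(scores),
            length(predictions) == length(truth))
  out <- lapply(cutoffs, function(ct) {
    classified <- !is.na(predictions) & !is.na(scores) & scores >= ct
    nC <- sum(classified)
    acc <- if (nC > 0) mean(predictions[classified] == truth[classified])
           else NA_real_
    data.frame(cutoff = ct, accuracy = acc,
               error = if (is.na(acc)) NA_real_ else 1 - acc,
               coverage = nC / length(predictions))
  })
  df <- do.call(rbind, out)
  attr(df, "mode") <- mode
  df
}

#' Label the outcome of one slide prediction
#'
#' Classifies a prediction against ground truth into the error taxonomy:
#' \describe{
#'   \item{\code{TYPE_A}}{non-lesional tissue misclassified as a lesion
#'     class;}
#'   \item{\code{TYPE_B}}{misclassification among trained classes of a
#'     trained, lesional truth (or a trained non-lesional truth called as
#'     another non-lesional class);}
#'   \item{\code{TYPE_C}}{a novel, previously untrained class called as any
#'     trained class;}
#'   \item{\code{EXCLUDED}}{slides with an uncertainty verdict
#'     (differential, undefined, insufficient lesional tissue) are not
#'     scored;}
#'   \item{\code{CORRECT}}{prediction matches the truth.}
#' }
#'
#' @param prediction a trained class name, or \code{NA} for an uncertainty
#'   verdict.
#' @param truthClass true class label (or \code{"NOVEL"}).
#' @param isLesional whether the truth is lesional tissue.
#' @param isTrained whether the truth class is in the trained set.
#' @param lesionClasses names of the trained lesion classes.
#' @param trainedClasses names of all trained classes.
#' @return one of \code{"CORRECT"}, \code{"TYPE_A"}, \code{"TYPE_B"},
#'   \code{"TYPE_C"}, \code{"EXCLUDED"}.
#' @export
typeErrors <- function(prediction, truthClass, isLesional, isTrained,
                       lesionClasses, trainedClasses) {
  if (is.na(prediction) || prediction %in%
      c("UNDEFINED", "DIFFERENTIAL", "INSUFFICIENT_LESIONAL"))
    return("EXCLUDED")
  if (!isTrained) return("TYPE_C")
  if (!truthClass %in% trainedClasses)
    stop("unknown truth label: ", truthClass)
  if (prediction == truthClass) return("CORRECT")
  if (!isLesional && prediction %in% lesionClasses) return("TYPE_A")
  "TYPE_B"
}

#' Evaluate a cohort of slide reports against ground truth
#'
#' Scores four classifiers per slide -- the map-based verdict
#' (\code{tsne}), the probability baseline (\code{prob}), the combined
#' concordance rule (\code{combined}) and the hybrid blend
#' (\code{hybrid}) -- producing per-slide outcomes under the error
#' taxonomy, macro mROC AUCs over trained-class slides, and
#' accuracy/coverage sweep curves.
#'
#' Slides with differential/undefined/insufficient verdicts are excluded
#' from accuracy and from the AUC of the map-based and combined
#' classifiers, mirroring how uncertain verdicts are handed to a human
#' rather than scored.
#'
#' @param reports list of [SlideReport-class] objects.
#' @param truth data.frame with columns \code{slide_id},
#'   \code{truth_class}, \code{is_lesional}, \code{is_trained} (see
#'   [writeTruthCSV()]).
#' @param lesionClasses names of trained lesion classes.
#' @param trainedClasses names of all trained classes; defaults to the
#'   classes scored in the first report.
#' @param cutoffs sweep cutoff grid.
#' @return An [EvaluationReport-class].
#' @export
evaluateSlides <- function(reports, truth, lesionClasses,
                           trainedClasses = NULL,
                           cutoffs = seq(0, 1, by = 0.05)) {
  if (is.null(trainedClasses)) trainedClasses <- names(reports[[1]]@probMeans)
  ids <- vapply(reports, function(r) r@slideId, character(1))
  tr <- truth[match(ids, truth$slide_id), ]
  if (anyNA(tr$slide_id)) stop("truth table is missing some slides")

  predOf <- function(r, method) {
    switch(method,
      tsne = if (r@decision@status == "DIAGNOSIS") r@decision@classes
             else NA_character_,
      prob = r@probTop,
      combined = if (r@combined == "UNDEFINED") NA_character_ else r@combined,
      hybrid = if (length(r@hybrid)) names(r@hybrid)[which.max(r@hybrid)]
               else NA_character_)
  }
  statusOf <- function(r, method) {
    if (r@decision@status == "INSUFFICIENT_LESIONAL") "INSUFFICIENT_LESIONAL"
    else if (method %in% c("tsne", "combined")) {
      if (method == "combined" && r@combined == "UNDEFINED") "UNDEFINED"
      else r@decision@status
    } else "DIAGNOSIS"
  }

  methods <- c("tsne", "prob", "combined", "hybrid")
  rows <- list()
  for (m in methods) {
    pred <- vapply(reports, predOf, character(1), method = m)
    stat <- vapply(reports, statusOf, character(1), method = m)
    outc <- mapply(function(p, s, tc, il, it) {
      if (s == "INSUFFICIENT_LESIONAL") "EXCLUDED"
      else typeErrors(p, tc, il, it, lesionClasses, trainedClasses)
    }, pred, stat, tr$truth_class, tr$is_lesional, tr$is_trained)
    rows[[m]] <- DataFrame(slide_id = ids, method = m, prediction = pred,
                           status = stat, truth = tr$truth_class,
                           outcome = unname(outc))
  }
  perSlide <- do.call(rbind, rows)

  ## AUCs over trained-class slides (uncertain verdicts excluded for the
  ## map-based and combined classifiers)
  scoreOf <- function(r, m) {
    v <- switch(m, tsne = r@tileFractions, prob = r@probMeans,
                combined = r@tileFractions, hybrid = r@hybrid)
    if (length(v)) v[trainedClasses] else
      stats::setNames(rep(NA_real_, length(trainedClasses)), trainedClasses)
  }
  aucs <- c()
  for (m in methods) {
    S <- t(vapply(reports, scoreOf, numeric(length(trainedClasses)), m = m))
    colnames(S) <- trainedClasses
    keep <- tr$is_trained & stats::complete.cases(S)
    if (m %in% c("tsne", "combined")) {
      st <- vapply(reports, statusOf, character(1), method = m)
      keep <- keep & st == "DIAGNOSIS"
    }
    auc <- tryCatch(mrocAuc(S[keep, , drop = FALSE], tr$truth_class[keep])$macro,
                    error = function(e) NA_real_)
    aucs[m] <- auc
  }

  ## cutoff sweeps for the probability and map-based modes
  probPred <- vapply(reports, predOf, character(1), method = "prob")
  probScore <- vapply(reports, function(r)
    if (length(r@probMeans)) max(r@probMeans) else NA_real_, numeric(1))
  tsnePred <- vapply(reports, predOf, character(1), method = "tsne")
  definedFrac <- vapply(reports, function(r)
    if (is.na(r@outlierFraction)) NA_real_ else 1 - r@outlierFraction,
    numeric(1))
  sweeps <- list(
    PROB_TOP_SCORE = accuracySweep(probPred, probScore, tr$truth_class,
                                   cutoffs, "PROB_TOP_SCORE"),
    TSNE_OUTLIER_FRACTION = accuracySweep(tsnePred, definedFrac,
                                          tr$truth_class, cutoffs,
                                          "TSNE_OUTLIER_FRACTION"))

  new("EvaluationReport", perSlide = perSlide, aucByMethod = aucs,
      sweeps = sweeps)
}

#' Write an evaluation report to disk
#'
#' Writes \code{per_slide.csv}, \code{auc.csv} and one sweep CSV
#' (\code{cutoff,accuracy,error,coverage}) per mode.
#'
#' @param evaluation an [EvaluationReport-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeEvaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(evaluation@perSlide),
                   file.path(dir, "per_slide.csv"), row.names = FALSE)
  utils::write.csv(data.frame(method = names(evaluation@aucByMethod),
                              auc = unname(evaluation@aucByMethod)),
                   file.path(dir, "auc.csv"), row.names = FALSE)
  for (m in names(evaluation@sweeps))
    utils::write.csv(evaluation@sweeps[[m]],
                     file.path(dir, sprintf("sweep_%s.csv", tolower(m))),
                     row.names = FALSE)
  invisible(dir)
}
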