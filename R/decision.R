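#' @include AllClasses.R
NULL

#' Chi-square goodness-of-fit test against an equal partition
#'
#' Tests whether observed category counts deviate from a random, equally
#' partitioned distribution over the same categories: statistic
#' \eqn{\sum_i (O_i - E)^2 / E} with \eqn{E = N/k} and \eqn{k - 1} degrees
#' of freedom. No continuity correction and no minimum-expected-count guard
#' are applied -- the procedure is routinely run on tables of 15-100 tiles.
#' A single category is non-informative and returns
#' \code{(statistic = 0, df = 0, p = 1)} by convention.
#'
#' @param counts non-negative integer vector of category counts.
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @examples
#' chi2Uniform(c(50, 50))$p.value        # 1
#' chi2Uniform(c(40, 35, 25))$statistic  # 3.5
#' @export
chi2Uniform <- function(counts) {
  counts <- unname(counts)
  if (length(counts) < 1L) stop("counts must have at least one category")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) stop("counts must be integers")
  total <- sum(counts)
  if (total < 1) stop("total count must be >= 1")
  k <- length(counts)
  if (k == 1L) return(list(statistic = 0, df = 0L, p.value = 1))
  E <- total / k
  stat <- sum((counts - E)^2 / E)
  list(statistic = stat, df = k - 1L,
       p.value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Render a slide verdict by iterative chi-square elimination
#'
#' Converts a slide's tile contingency table into a graded verdict:
#' \enumerate{
#'   \item \emph{Outlier check}: the full table (outlier category included)
#'     is tested against an equal partition. If the distribution is
#'     significant (\code{p < alpha}) \emph{and} the outlier category holds
#'     the most tiles, the slide contains too many novel/anomalous features
#'     and is \code{UNDEFINED}.
#'   \item The outlier category is then set aside (a differential diagnosis
#'     is a list of diagnosable classes); if nothing remains the slide is
#'     \code{UNDEFINED}.
#'   \item \emph{Iterative elimination}: while the remaining class
#'     distribution differs significantly from uniform, the class with the
#'     fewest tiles is removed (ties by label order) and the rest retested.
#'     A single surviving class is the \code{DIAGNOSIS}; a non-significant
#'     multi-class remainder is reported as the \code{DIFFERENTIAL}
#'     diagnosis, ordered by tile count.
#' }
#' The significance level is fixed a priori, so no post-hoc cutoff tuning
#' enters the verdict.
#'
#' @param table named tile counts per category, possibly including
#'   \code{OUTLIER_LABEL} (see [tabulateAssignments()]).
#' @param alpha significance level (default 0.01).
#' @param outlierLabel name of the outlier category.
#' @return A [SlideDecision-class] with the full statistical trail.
#' @examples
#' decideSlide(c(glioma = 90, meningioma = 5, lymphoma = 5))
#' @export
decideSlide <- function(table, alpha = 0.01, outlierLabel = OUTLIER_LABEL) {
  if (length(table) == 0L) stop("contingency table is empty")
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stop("contingency table must be named")
  table <- table[table > 0]
  if (length(table) == 0L) stop("contingency table holds no tiles")

  trail <- data.frame(iteration = integer(0), classes = character(0),
                      counts = character(0), statistic = numeric(0),
                      df = integer(0), p.value = numeric(0),
                      removed = character(0), stringsAsFactors = FALSE)
  note <- function(it, tb, t, removed) {
    rbind(trail, data.frame(
      iteration = it, classes = paste(names(tb), collapse = ","),
      counts = paste(tb, collapse = ","), statistic = t$statistic,
      df = t$df, p.value = t$p.value, removed = removed,
      stringsAsFactors = FALSE))
  }

  ## Step 1: first-iteration outlier check on the full table
  t0 <- chi2Uniform(table)
  ## the outlier category is modal iff no class holds more tiles than it
  ## (ties count as modal), independent of table ordering
  outlierModal <- outlierLabel %in% names(table) &&
    table[[outlierLabel]] == max(table)
  trail <- note(0L, table, t0, NA_character_)
  if (t0$p.value < alpha && outlierModal)
    return(new("SlideDecision", status = "UNDEFINED", classes = character(0),
               trail = trail, alpha = alpha))

  ## Step 2: outliers set aside
  tb <- table[names(table) != outlierLabel]
  if (length(tb) == 0L)
    return(new("SlideDecision", status = "UNDEFINED", classes = character(0),
               trail = trail, alpha = alpha))

  ## Step 3: iterative elimination over diagnosable classes
  it <- 1L
  repeat {
    if (length(tb) == 1L)
      return(new("SlideDecision", status = "DIAGNOSIS", classes = names(tb),
                 trail = trail, alpha = alpha))
    t <- chi2Uniform(tb)
    if (t$p.value >= alpha) {
      ord <- order(-as.numeric(tb), names(tb))
      trail <- note(it, tb, t, NA_character_)
      return(new("SlideDecision", status = "DIFFERENTIAL",
                 classes = names(tb)[ord], trail = trail, alpha = alpha))
    }
    drop_i <- order(as.numeric(tb), names(tb))[1]  # fewest tiles, ties by label
    trail <- note(it, tb, t, names(tb)[drop_i])
    tb <- tb[-drop_i]
    it <- it + 1L
  }
}

#' Probability-score baseline diagnosis
#'
#' The traditional softmax readout: per-class probability scores of the
#' gated (lesion-enriched) tiles are averaged and the top-ranked class is
#' the prediction. Ties go to the earlier class in column order.
#'
#' @param probs tiles x classes probability matrix (gated tiles).
#' @return list with \code{means} (named mean vector) and \code{top} (class
#'   name).
#' @export
probabilityDiagnosis <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0L) stop("no gated tiles to average")
  m <- colMeans(probs)
  top <- names(m)[which.max(m)]
  if (is.null(top)) top <- as.character(which.max(m))
  list(means = m, top = top)
}

#' Combined (concordance) classification
#'
#' The conservative composite rule: a slide is classified only when the
#' map-based verdict is a single diagnosis \emph{and} the probability
#' baseline independently ranks the same class first; any discordance or
#' uncertainty yields \code{"UNDEFINED"}.
#'
#' @param decision a [SlideDecision-class].
#' @param probTop top class of the probability baseline.
#' @return the agreed class name, or \code{"UNDEFINED"}.
#' @export
combinedDecision <- function(decision, probTop) {
  if (decision@status == "DIAGNOSIS" && !is.na(probTop) &&
      identical(decision@classes, probTop))
    decision@classes
  else "UNDEFINED"
}

#' Hybrid blended score
#'
#' Blends the two per-class evidence vectors of a slide -- the fraction of
#' discretized tiles per class (outlier tiles excluded from numerator and
#' denominator) and the mean softmax probability -- into
#' \eqn{s_c = w \cdot frac_c + (1 - w) \cdot meanprob_c}.
#'
#' @param tileFractions named per-class assigned-tile fractions.
#' @param probMeans named per-class mean probabilities (same class order).
#' @param w weight of the tile-fraction term, in \[0, 1\] (default 0.5).
#' @return named blended score vector.
#' @export
hybridScores <- function(tileFractions, probMeans, w = 0.5) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (length(tileFractions) != length(probMeans))
    stop("tileFractions and probMeans differ in length")
  if (!is.null(names(tileFractions)) && !is.null(names(probMeans)) &&
      !identical(names(tileFractions), names(probMeans)))
    stop("tileFractions and probMeans must use the same class order")
  w * tileFractions + (1 - w) * probMeans
}
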