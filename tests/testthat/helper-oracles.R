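# Independent oracle implementations used to cross-check the package.
# These deliberately take different code paths from the implementation
# (chisq.test instead of the closed-form statistic; explicit full sorts
# instead of partial neighbour lookup; pair counting instead of trapezoids).

# Brute-force re-implementation of the iterative chi-square verdict.
oracle_decide <- function(tb, alpha = 0.01, out = "OUTLIER") {
  tb <- tb[tb > 0]
  p_of <- function(v) {
    if (length(v) == 1L) return(1)
    suppressWarnings(
      stats::chisq.test(as.numeric(v), p = rep(1 / length(v), length(v)))$p.value)
  }
  if (out %in% names(tb) && p_of(tb) < alpha && tb[[out]] == max(tb))
    return(list(status = "UNDEFINED", classes = character(0)))
  tb <- tb[names(tb) != out]
  if (!length(tb)) return(list(status = "UNDEFINED", classes = character(0)))
  while (length(tb) > 1L && p_of(tb) < alpha) {
    o <- names(tb)[order(as.numeric(tb), names(tb))][1]
    tb <- tb[names(tb) != o]
  }
  if (length(tb) == 1L) list(status = "DIAGNOSIS", classes = names(tb))
  else list(status = "DIFFERENTIAL",
            classes = names(tb)[order(-as.numeric(tb), names(tb))])
}

# Full-sort k-nearest-neighbour call for a single query point.
oracle_assign <- function(q, ref, labels, k = 25L, purity = 0.85,
                          out = "OUTLIER") {
  d <- sqrt(colSums((t(ref) - q)^2))
  df <- data.frame(i = seq_along(d), d = d, lab = labels)
  df <- df[order(df$d, df$i), ]
  nb <- df$lab[seq_len(k)]
  tb <- sort(table(nb), decreasing = TRUE)
  cand <- names(tb)[tb == max(tb)]
  top <- sort(cand)[1]
  frac <- max(tb) / k
  list(call = if (frac >= purity) top else out, purity = frac,
       neighbors = df$i[seq_len(k)])
}

# Mann-Whitney pair-counting AUC with half-credit for ties.
oracle_auc <- function(score, positive) {
  sp <- score[positive]
  sn <- score[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Small, fast fixture configurations used across tests.
tiny_config <- function(seed = 7, nClasses = 4L, featureDim = 48L,
                        npc = 30L, lesionClassIds = 1:2) {
  fixtureConfig(nClasses = nClasses, featureDim = featureDim,
                tilesPerClassRange = c(npc, npc),
                lesionClassIds = lesionClassIds, seed = seed)
}

# Desk-scale study configuration shared by the heavier end-to-end and
# acceptance tests (13 classes, CNN-scale dimensionality, 50 tiles/class).
study_config <- function(seed = 1L) {
  fixtureConfig(featureDim = 1024L, tilesPerClassRange = c(50L, 50L),
                seed = seed)
}

study_pipeline_config <- function(seed = 1L) {
  pipelineConfig(seed = seed, nCheckNeighbors = 50L)
}
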