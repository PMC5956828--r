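## Internal helpers shared across modules.

## Evaluate expr under a local, restored RNG state so generator and pipeline
## functions are pure functions of their seed argument.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Derive a per-slide 31-bit sub-seed from a base seed and a string key, so
## that classifying the same slide under the same config is reproducible
## while different slides draw different samples.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

## Squared Euclidean distances from one point to the rows of a matrix.
sqdist_to <- function(x, M) {
  d <- sweep(M, 2, x)
  rowSums(d * d)
}

## Indices of the k nearest rows of `ref` to point `x` (2-D or n-D),
## deterministic under distance ties (stable order by row index).
knn_indices <- function(x, ref, k) {
  d2 <- sqdist_to(x, ref)
  order(d2, seq_along(d2))[seq_len(k)]
}

## Softmax of -d^2 / temperature against a matrix of class means; the mock
## probability model used throughout the fixture generator.
softmax_class_probs <- function(x, means, temperature = 1) {
  z <- -sqdist_to(x, means) / temperature
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

## Format a named count vector as "a=1, b=2" for trails and messages.
fmt_counts <- function(counts) {
  paste(names(counts), counts, sep = "=", collapse = ", ")
}
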