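# Shared fixtures and independent oracles used across the test files.

# Brute-force Cliff's Delta: enumerate every cross pair.
brute_cliffs <- function(a, b) {
  mean(sign(outer(a, b, `-`)))
}

# Exact binomial upper tail P(X >= c) by explicit term summation (independent
# of pbinom).
binom_tail_sum <- function(c, n, p) {
  if (c <= 0) return(1)
  sum(vapply(c:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

make_trace <- function(values, fs = 1000) {
  tibble::tibble(time = (seq_along(values) - 1) / fs, value = values)
}

make_trinary <- function(codes, fs = 1000) {
  tibble::tibble(time = (seq_along(codes) - 1) / fs, code = as.integer(codes))
}

# Recall/precision of detected event onsets against ground truth.
match_events <- function(detected, truth, tol = 0.007) {
  recall <- if (length(truth) == 0) 1 else {
    mean(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
  }
  precision <- if (length(detected) == 0) 1 else {
    mean(vapply(detected, function(t) any(abs(truth - t) <= tol), logical(1)))
  }
  list(recall = recall, precision = precision)
}

# Two clusterings agree as partitions (identical co-membership structure).
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ca <- outer(a, a, `==`)
  cb <- outer(b, b, `==`)
  all(ca == cb)
}

# Minimal cluster_result for significance tests with controlled counts.
fake_cluster_result <- function(labels, k = max(labels)) {
  structure(
    list(labels = tibble::tibble(animal = seq_along(labels), cluster = labels),
         k = k, hclust = NULL, cosine = NULL, groups = NULL),
    class = "cluster_result"
  )
}
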