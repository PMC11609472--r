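# Small fixtures built in code, shared across test files.

# perfectly separable 2-class, 1-feature data
toy_separable <- function() {
  tibble::tibble(x = c(1, 2, 3, 4), cls = factor(c("a", "a", "b", "b")))
}

# 2-class, 2-feature linearly separable toy
toy_two_feature <- function(n_per = 10, seed = 7) {
  withr::with_seed(seed, {
    tibble::tibble(
      x1 = c(rnorm(n_per, -2, 0.5), rnorm(n_per, 2, 0.5)),
      x2 = rnorm(2 * n_per),
      cls = factor(rep(c("a", "b"), each = n_per)))
  })
}

# brute-force best split: enumerate every midpoint of adjacent sorted
# distinct values, compute gain directly from impurity definitions
brute_best_split <- function(x, y, mode = "classification") {
  xs <- sort(unique(x))
  if (length(xs) < 2) return(NULL)
  thr <- (xs[-1] + xs[-length(xs)]) / 2
  gini <- function(v) {
    tab <- table(v)
    1 - sum((tab / sum(tab))^2)
  }
  sse <- function(v) sum((v - mean(v))^2)
  gains <- vapply(thr, function(t) {
    l <- y[x <= t]; r <- y[x > t]
    if (mode == "classification") {
      gini(y) - (length(l) * gini(l) + length(r) * gini(r)) / length(y)
    } else {
      sse(y) - (sse(l) + sse(r))
    }
  }, numeric(1))
  best <- which.max(gains)
  list(threshold = thr[best], gain = gains[best])
}

# deterministic hand-built depth-1 tree for routing / proximity tests
hand_stump <- function(threshold, classes = c("a", "b"),
                       counts_left = c(2L, 0L), counts_right = c(0L, 2L)) {
  structure(list(
    nodes = list(
      list(id = 1L, is_leaf = FALSE, feature = 1L, neighbourhood = 1L,
           loadings = 1, center = 0, threshold = threshold,
           left = 2L, right = 3L,
           counts_parent = counts_left + counts_right,
           counts_left = counts_left, counts_right = counts_right,
           impurity_decrease = 0.5),
      list(id = 2L, is_leaf = TRUE, counts = counts_left,
           value = which.max(counts_left), n = sum(counts_left)),
      list(id = 3L, is_leaf = TRUE, counts = counts_right,
           value = which.max(counts_right), n = sum(counts_right))),
    root = 1L, mode = "classification",
    root_counts = counts_left + counts_right, n_groups = length(classes),
    train_leaf = integer(0), p = 1L, class_list = classes,
    feature_names = "x"), class = "clifi_tree")
}
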