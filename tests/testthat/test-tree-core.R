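test_that("gini impurity matches closed forms and rejects degenerate nodes", {
  expect_equal(gini_impurity(c(5, 0)), 0)
  expect_equal(gini_impurity(c(2, 2)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "degenerate")
  expect_error(gini_impurity(c(-1, 2)), "negative")
})

test_that("best split on a separable column is the separating midpoint", {
  sp <- find_best_split(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                        "classification")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$gain, 0.5)
})

test_that("constant columns yield the no-split sentinel", {
  expect_null(find_best_split(c(1, 1, 1), c("a", "b", "a"),
                              "classification"))
  expect_null(find_best_split(rep(2, 5), rnorm(5), "regression"))
})

test_that("split search agrees with brute-force enumeration", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(3:30, 1)
      x <- round(rnorm(n), 1)              # duplicates likely
      y <- sample(letters[1:3], n, replace = TRUE)
      oracle <- brute_best_split(x, y)
      got <- find_best_split(x, y, "classification")
      if (is.null(oracle)) {
        expect_null(got)
      } else {
        expect_equal(got$gain, oracle$gain, tolerance = 1e-12)
      }
      r <- rnorm(n)
      oracle_r <- brute_best_split(x, r, "regression")
      got_r <- find_best_split(x, r, "regression")
      if (!is.null(oracle_r) && !is.null(got_r)) {
        expect_equal(got_r$gain, oracle_r$gain, tolerance = 1e-9)
      }
    }
  })
})

test_that("latent scores centre, project and fix signs as documented", {
  ls1 <- lava_latent_scores(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(ls1$loadings, 1)
  expect_equal(ls1$scores, c(-1, 0, 1))

  ls2 <- lava_latent_scores(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ls2$loadings, rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(ls2$scores, c(-sqrt(2), 0, sqrt(2)), tolerance = 1e-10)

  # oracle: independent decomposition via prcomp
  X <- matrix(c(0, 0, 1, 2, 2, 1), nrow = 3, byrow = TRUE)
  ls3 <- lava_latent_scores(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  expect_equal(ls3$loadings, unname(v), tolerance = 1e-10)
  expect_equal(ls3$scores, unname(as.vector(scale(X, scale = FALSE) %*% v)),
               tolerance = 1e-10)
  expect_equal(sum(ls3$loadings^2), 1, tolerance = 1e-12)

  # zero-variance fallback: unit loading on the anchor, zero scores
  ls4 <- lava_latent_scores(matrix(1, 3, 2), anchor = 2L)
  expect_equal(ls4$loadings, c(0, 1))
  expect_equal(ls4$scores, c(0, 0, 0))
})

test_that("grow_tree splits separable data into pure leaves", {
  tr <- grow_tree(toy_separable(), cls, max_features = "all", seed = 1)
  internal <- Filter(function(n) !n$is_leaf, tr$nodes)
  leaves <- Filter(function(n) n$is_leaf, tr$nodes)
  expect_length(internal, 1)
  expect_length(leaves, 2)
  expect_equal(internal[[1]]$threshold, 2.5)
  counts <- lapply(leaves, `[[`, "counts")
  expect_setequal(vapply(counts, paste, character(1), collapse = ","),
                  c("2,0", "0,2"))
})

test_that("pure-label data yields a single leaf with no split records", {
  d <- tibble::tibble(x = c(1, 5, 2), cls = factor(c("a", "a", "a")))
  tr <- grow_tree(d, cls, seed = 1)
  expect_length(tr$nodes, 1)
  expect_true(tr$nodes[[1]]$is_leaf)
})

test_that("child class counts sum to parent counts at every split", {
  d <- iris_with_noise(seed = 4)
  tr <- grow_tree(d, species, max_features = "sqrt", seed = 4)
  for (node in tr$nodes) {
    if (!node$is_leaf) {
      expect_equal(node$counts_left + node$counts_right,
                   node$counts_parent)
      expect_gte(node$impurity_decrease, 0)
    }
  }
})

test_that("identity neighbourhoods grow bit-identical trees to plain mode", {
  d <- iris_with_noise(seed = 5)
  t1 <- grow_tree(d, species, max_features = "sqrt", seed = 3)
  t2 <- grow_tree(d, species, max_features = "sqrt", seed = 3,
                  neighbourhoods = identity_neighbourhoods(7))
  expect_identical(t1$nodes, t2$nodes)
})

test_that("apply_tree reproduces training leaves and routes latent nodes", {
  d <- toy_two_feature()
  tr <- grow_tree(d, cls, max_features = "all", seed = 2)
  routed <- apply_tree(tr, d)
  expect_equal(routed$leaf_id, tr$train_leaf)
  expect_equal(as.character(routed$.pred_class), as.character(d$cls))

  stump <- hand_stump(threshold = 2.5)
  expect_equal(apply_tree(stump, matrix(2))$leaf_id, 2L)
  expect_equal(apply_tree(stump, matrix(3))$leaf_id, 3L)

  # latent node: projection (3,3) - (2,2) onto (0.70711, 0.70711) is > 0
  lava_node <- hand_stump(threshold = 0)
  lava_node$nodes[[1]]$neighbourhood <- c(1L, 2L)
  lava_node$nodes[[1]]$loadings <- rep(1 / sqrt(2), 2)
  lava_node$nodes[[1]]$center <- c(2, 2)
  lava_node$p <- 2L
  expect_equal(apply_tree(lava_node, matrix(c(3, 3), 1))$leaf_id, 3L)
  expect_error(apply_tree(stump, matrix(1, 1, 3)), "feature columns")
})
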