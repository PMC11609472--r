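test_that("g_test matches direct evaluation and honours the O > 0 rule", {
  expect_equal(g_test(c(10, 10), c(10, 10)), 0)
  expect_equal(g_test(c(15, 5), c(10, 10)),
               2 * (15 * log(1.5) + 5 * log(0.5)), tolerance = 1e-12)
  expect_equal(round(g_test(c(15, 5), c(10, 10)), 5), 5.23248)
  # zero observed category skipped entirely
  expect_equal(g_test(c(20, 0), c(10, 10)), 2 * 20 * log(2),
               tolerance = 1e-12)
  expect_equal(round(g_test(c(20, 0), c(10, 10)), 5), 27.72589)
  expect_error(g_test(c(5, 1), c(5, 0)), "expected = 0")
})

test_that("partial_g matches its closed form and drops zero counts", {
  expect_equal(partial_g(2, 4), 0)
  expect_equal(partial_g(1, 4), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(round(partial_g(1, 4), 5), -1.38629)
  expect_equal(round(partial_g(3, 4), 5), 2.43279)
  expect_equal(partial_g(0, 4), 0)
  expect_error(partial_g(1, 0), "parent")
  expect_error(partial_g(5, 4), "child")
})

test_that("split importance hits the analytic anchors", {
  # all of the class to the right of a root split
  expect_equal(clifi_for_split(left = 0, right = 8, ancestor = 8), 1)
  # all to the left
  expect_equal(clifi_for_split(left = 8, right = 0, ancestor = 8), -1)
  # exactly balanced
  expect_equal(clifi_for_split(left = 4, right = 4, ancestor = 10), 0)
  # worked intermediate case
  expect_equal(clifi_for_split(left = 1, right = 3, ancestor = 8),
               (3 * log(1.5) + log(0.5)) / (8 * log(2)), tolerance = 1e-12)
  expect_equal(round(clifi_for_split(left = 1, right = 3, ancestor = 8), 5),
               0.09436)
  # classes absent from the node score 0
  expect_equal(clifi_for_split(left = c(0, 1), right = c(0, 3),
                               ancestor = c(5, 8))[1], 0)
  expect_error(clifi_for_split(left = 2, right = 2, parent = 5,
                               ancestor = 8), "left \\+ right")
})

test_that("split importance equals the partial-g composition on random counts", {
  withr::with_seed(31, {
    for (i in 1:500) {
      P <- sample(1:40, 1)
      L <- sample(0:P, 1)
      R <- P - L
      A <- P + sample(0:40, 1)
      got <- clifi_for_split(left = L, right = R, ancestor = A)
      m1 <- partial_g(L, P)
      m2 <- partial_g(R, P)
      expect_equal(got, (m1 + m2) / (2 * A * log(2)) * sign(m2 - m1),
                   tolerance = 1e-12)
      # bound |value| <= P/A <= 1
      expect_lte(abs(got), P / A + 1e-12)
      # mirror antisymmetry
      expect_equal(clifi_for_split(left = R, right = L, ancestor = A), -got,
                   tolerance = 1e-12)
      # scale invariance
      c_mult <- sample(2:5, 1)
      expect_equal(clifi_for_split(left = c_mult * L, right = c_mult * R,
                                   ancestor = c_mult * A), got,
                   tolerance = 1e-12)
    }
  })
})

test_that("|importance| grows monotonically as the split becomes one-sided", {
  P <- 12; A <- 20
  vals <- vapply(6:0, function(L) {
    abs(clifi_for_split(left = L, right = P - L, ancestor = A))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("loading distribution preserves total mass and flips signs", {
  expect_equal(distribute_to_original_features(0.7, 1), 0.7)
  expect_equal(distribute_to_original_features(0.7, c(0.8, -0.6)),
               c(0.4, -0.3), tolerance = 1e-12)
  expect_equal(distribute_to_original_features(-1, c(0.5, 0.5)),
               c(-0.5, -0.5))
  out <- distribute_to_original_features(0.7, c(0.8, -0.6), signed = FALSE)
  expect_equal(out, c(0.4, 0.3), tolerance = 1e-12)
  expect_equal(sum(abs(out)), 0.7, tolerance = 1e-12)
  expect_error(distribute_to_original_features(1, c(0, 0)), "zero")
})

test_that("error-label rescaling is the weighted sum of label values", {
  expect_equal(clifi_boosting_rescale(0.4, 1), 0.4)
  expect_equal(clifi_boosting_rescale(c(0.5, -0.5), c(0.6, 0.4)), 0.1,
               tolerance = 1e-12)
  expect_equal(clifi_boosting_rescale(c(0, 0), c(0.3, 0.7)), 0)
  expect_error(clifi_boosting_rescale(c(1, 2), 1), "align")
})

test_that("a perfect depth-1 split yields +1 and -1 records at the root", {
  d <- toy_separable()
  fit <- clifi_forest(d, cls, n_trees = 1, sample_fraction = 1,
                      max_features = "all", seed = 1)
  tab <- collect_clifi(fit)
  recs <- tab$records[order(tab$records$class), ]
  expect_equal(nrow(recs), 2)
  expect_equal(recs$value[recs$class == "a"], -1)  # class a below threshold
  expect_equal(recs$value[recs$class == "b"], 1)
})

test_that("identity-neighbourhood models give identical CLIFI tables", {
  d <- iris_with_noise(seed = 10)
  f1 <- clifi_forest(d, species, n_trees = 5, seed = 19)
  f2 <- clifi_forest(d, species, n_trees = 5, seed = 19,
                     neighbourhoods = identity_neighbourhoods(7))
  expect_identical(collect_clifi(f1)$records, collect_clifi(f2)$records)
  b1 <- clifi_boost(d, species, n_rounds = 2, seed = 19)
  b2 <- clifi_boost(d, species, n_rounds = 2, seed = 19,
                    neighbourhoods = identity_neighbourhoods(7))
  expect_identical(collect_clifi(b1)$records, collect_clifi(b2)$records)
})

test_that("aggregation sums records and normalises by the maximum", {
  recs <- tibble::tibble(
    tree_id = c(1L, 1L, 2L), node_id = 1L,
    feature = c("f1", "f1", "f2"), class = c("a", "a", "b"),
    value = c(0.5, -1.5, 2))
  tab <- new_clifi_table(recs, feature_names = c("f1", "f2"),
                         class_list = c("a", "b"))
  expect_equal(tab$aclifi["f1", "a"], -1)
  expect_equal(tab$aclifi["f2", "b"], 2)
  expect_equal(tab$naclifi["f1", "a"], -0.5)
  expect_equal(tab$naclifi["f2", "b"], 1)
  expect_equal(max(abs(tab$naclifi)), 1)

  single <- new_clifi_table(recs[1, ], feature_names = "f1",
                            class_list = "a")
  expect_equal(single$aclifi["f1", "a"], 0.5)
  expect_equal(single$naclifi["f1", "a"], 1)
})

test_that("top-feature selection applies the strict mean filter per direction", {
  recs <- tibble::tibble(
    tree_id = 1L, node_id = 1L,
    feature = c("f1", "f2", "f3"), class = "a",
    value = c(0.9, 0.5, 0.1))
  tab <- new_clifi_table(recs, class_list = "a")
  sel <- select_top_features(tab, "a")
  expect_equal(sel$feature, "f1")   # mean of positives is 0.5; strict >
  expect_equal(nrow(select_top_features(tab, "a", direction = "negative")),
               0)
  expect_equal(nrow(select_top_features(tab, "a", k = 1)), 1)
})

test_that("class-difference testing follows KW -> pairwise MWU -> BH", {
  # strongly separated classes: pairwise test must fire
  withr::with_seed(41, {
    recs <- tibble::tibble(
      tree_id = rep(1:40, 2), node_id = 1L, feature = "f1",
      class = rep(c("a", "b"), each = 40),
      value = c(rnorm(40, 0.8, 0.05), rnorm(40, -0.8, 0.05)))
  })
  tab <- new_clifi_table(recs, class_list = c("a", "b"))
  out <- class_difference_tests(tab)
  pw <- out[out$test == "wilcoxon", ]
  expect_equal(nrow(pw), 1)
  expect_lt(pw$p_adj, 0.05)

  # identical distributions: omnibus must not fire
  withr::with_seed(42, {
    null_recs <- tibble::tibble(
      tree_id = rep(1:30, 2), node_id = 1L, feature = "f1",
      class = rep(c("a", "b"), each = 30), value = rnorm(60))
  })
  out2 <- class_difference_tests(new_clifi_table(null_recs,
                                                 class_list = c("a", "b")))
  expect_gt(out2$p_adj[out2$test == "kruskal"], 0.05)

  # features with too few records are skipped with a message
  tiny <- tibble::tibble(tree_id = 1L, node_id = 1L, feature = "f9",
                         class = c("a", "b"), value = c(0.1, 0.2))
  expect_message(
    out3 <- class_difference_tests(new_clifi_table(tiny,
                                                   class_list = c("a", "b"))),
    "fewer than 2 classes")
  expect_equal(nrow(out3), 0)
})

test_that("BH adjustment reproduces the hand-evaluated step-up example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
})

test_that("boosted CLIFI respects the error-label weighting", {
  # one booster round on a separable toy: root regression split separates
  # the classes, so error labels coincide with classes
  d <- toy_two_feature()
  fit <- clifi_boost(d, cls, n_rounds = 1, max_features = "all", seed = 5)
  tab <- collect_clifi(fit)
  acl <- tab$aclifi
  # class a sits at low x1, class b at high x1: signs must oppose
  expect_lt(acl["x1", "a"], 0)
  expect_gt(acl["x1", "b"], 0)
})
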