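test_that("three-way split follows largest-remainder arithmetic", {
  d <- tibble::tibble(x = rnorm(30),
                      cls = factor(rep(c("a", "b", "c"), each = 10)))
  sp <- stratified_three_way_split(d, cls, test_fraction = 0.3,
                                   val_fraction = 0.2, seed = 1)
  # 10 per class: test gets exactly 3 per class; remainder 7 -> val 1-2,
  # train 5-6 per class
  per_class <- function(idx) table(d$cls[idx])
  expect_equal(unname(per_class(sp$test)), rep(3L, 3), ignore_attr = TRUE)
  expect_true(all(per_class(sp$val) %in% 1:2))
  expect_true(all(per_class(sp$train) %in% 5:6))
  expect_equal(sum(per_class(sp$val)), round(0.2 * 21))
})

test_that("splits are disjoint, exhaustive, and seed-deterministic", {
  d <- iris_with_noise(seed = 1)
  sp <- stratified_three_way_split(d, species, seed = 5)
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all_idx), seq_len(nrow(d)))
  expect_equal(anyDuplicated(all_idx), 0)
  expect_identical(sp, stratified_three_way_split(d, species, seed = 5))
  expect_false(identical(sp, stratified_three_way_split(d, species,
                                                        seed = 6)))
  expect_error(
    stratified_three_way_split(
      tibble::tibble(x = 1:4, cls = c("a", "a", "a", "b")), cls),
    "fewer than 3")
})

test_that("classification metrics match hand-computed confusion tables", {
  rep1 <- classification_report(c("a", "a", "b", "b"),
                                c("a", "a", "b", "b"))
  expect_true(all(rep1$value[is.na(rep1$class)] == 1))

  # confusion [[2,0],[1,1]]: accuracy 75%, weighted recall 75%
  rep2 <- classification_report(c("a", "a", "b", "b"),
                                c("a", "a", "a", "b"))
  get <- function(m) rep2$value[rep2$metric == m & is.na(rep2$class)]
  expect_equal(get("accuracy"), 0.75)
  expect_equal(get("recall_weighted"), 0.75)
  expect_equal(get("precision_weighted"), (0.5 * 2 / 3 + 0.5 * 1))

  # all-one-class predictions on balanced data: 50% accuracy
  rep3 <- classification_report(c("a", "b", "a", "b"), rep("a", 4),
                                class_list = c("a", "b"))
  expect_equal(rep3$value[rep3$metric == "accuracy"], 0.5)
  # never-predicted class contributes precision 0
  expect_equal(rep3$value[rep3$metric == "precision" & rep3$class == "b"], 0)

  expect_error(classification_report(c("a", "z"), c("a", "a"),
                                     class_list = c("a", "b")), "outside")
})

test_that("weighted metrics agree with an independent reference", {
  skip_if_not_installed("caret")
  withr::with_seed(61, {
    truth <- factor(sample(letters[1:4], 200, replace = TRUE))
    est <- factor(ifelse(runif(200) < 0.6, as.character(truth),
                         sample(letters[1:4], 200, replace = TRUE)),
                  levels = letters[1:4])
  })
  rep_tbl <- classification_report(truth, est, levels(truth))
  cm <- caret::confusionMatrix(est, truth, mode = "prec_recall")
  support <- as.vector(table(truth))
  ref_prec <- sum(cm$byClass[, "Precision"] * support / sum(support),
                  na.rm = TRUE)
  ref_rec <- sum(cm$byClass[, "Recall"] * support / sum(support))
  ref_f1 <- sum(cm$byClass[, "F1"] * support / sum(support), na.rm = TRUE)
  get <- function(m) rep_tbl$value[rep_tbl$metric == m & is.na(rep_tbl$class)]
  expect_equal(get("accuracy"), unname(cm$overall["Accuracy"]))
  expect_equal(get("precision_weighted"), ref_prec, tolerance = 1e-10)
  expect_equal(get("recall_weighted"), ref_rec, tolerance = 1e-10)
  expect_equal(get("f1_weighted"), ref_f1, tolerance = 1e-10)
})

test_that("the pipeline writes its artifact contract and is reproducible", {
  out1 <- withr::local_tempdir()
  config <- list(algorithm = "rf", dataset = "iris_with_noise",
                 seeds = c(1L, 2L), n_trees = 10L)
  res <- run_pipeline(config, outdir = out1)
  expect_true(all(file.exists(unlist(res$paths))))
  metrics <- readr::read_csv(res$paths$metrics, show_col_types = FALSE)
  # 2 seeds x 2 subsets x 5 aggregate metrics, plus summary rows
  expect_equal(sum(metrics$row == "run"), 2 * 2 * 5)
  expect_equal(sum(metrics$row == "summary"), 2 * 5)
  expect_true(all(metrics$value[metrics$row == "run"] >= 0 &
                    metrics$value[metrics$row == "run"] <= 100))

  out2 <- withr::local_tempdir()
  run_pipeline(config, outdir = out2)
  expect_identical(readr::read_csv(file.path(out2, "metrics.csv"),
                                   show_col_types = FALSE), metrics)
  # summary reproduces hand computation on the per-run rows
  runs <- metrics[metrics$row == "run", ]
  summ <- metrics[metrics$row == "summary", ]
  for (i in seq_len(nrow(summ))) {
    v <- runs$value[runs$subset == summ$subset[i] &
                      runs$metric == summ$metric[i]]
    expect_equal(summ$mean[i], mean(v))
    expect_equal(summ$sd[i], stats::sd(v))
  }
})

test_that("config schema violations and file configs are handled", {
  expect_error(run_pipeline(list(algorithm = "rf", bogus_key = 1),
                            outdir = withr::local_tempdir()),
               "bogus_key")
  cfg_file <- withr::local_tempfile(lines = c(
    "algorithm=rf", "dataset=iris_with_noise", "seeds=3", "n_trees=5",
    "# a comment", ""))
  out <- withr::local_tempdir()
  res <- run_pipeline(cfg_file, outdir = out)
  expect_true(file.exists(res$paths$metrics))
})

test_that("a theta = 0 LAVA pipeline matches the plain pipeline exactly", {
  out_rf <- withr::local_tempdir()
  out_lv <- withr::local_tempdir()
  base <- list(dataset = "iris_with_noise", seeds = 4L, n_trees = 8L)
  run_pipeline(c(base, list(algorithm = "rf")), outdir = out_rf)
  run_pipeline(c(base, list(algorithm = "lavaset", theta = 0)),
               outdir = out_lv)
  m_rf <- readr::read_csv(file.path(out_rf, "metrics.csv"),
                          show_col_types = FALSE)
  m_lv <- readr::read_csv(file.path(out_lv, "metrics.csv"),
                          show_col_types = FALSE)
  expect_identical(m_rf, m_lv)
})

test_that("the pipeline runs end-to-end on a user-supplied matrix", {
  withr::with_seed(71, {
    df <- tibble::tibble(
      p1 = rnorm(60), p2 = rnorm(60), p3 = rnorm(60),
      group = factor(rep(c("x", "y", "z"), each = 20)))
    df$p1 <- df$p1 + 2 * (df$group == "x")
  })
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, csv)
  out <- withr::local_tempdir()
  res <- run_pipeline(list(algorithm = "gbdt", dataset = csv,
                           label = "group", seeds = 1L, rounds = 3L),
                      outdir = out)
  expect_true(all(file.exists(unlist(res$paths))))
  recs <- readr::read_csv(file.path(out, "clifi_records.csv"),
                          show_col_types = FALSE)
  expect_true(all(c("tree_id", "node_id", "feature", "class", "value")
                  %in% names(recs)))
})

test_that("grid search picks the best validation F1, ties to smaller models", {
  d <- iris_with_noise(seed = 16)
  sp <- stratified_three_way_split(d, species, seed = 2)
  out <- hyperparameter_search(d, species, "rf", n_trees = c(5L, 10L),
                               split = sp, seed = 2)
  expect_equal(nrow(out$results), 2)
  expect_equal(out$best$f1_weighted, max(out$results$f1_weighted))
  # a degenerate grid with identical scores resolves to the smaller model
  out2 <- hyperparameter_search(d, species, "rf", n_trees = c(7L, 7L),
                                split = sp, seed = 2)
  expect_equal(out2$best$n_trees, 7L)
  out3 <- hyperparameter_search(d, species, "gbdt", n_rounds = c(2L, 3L),
                                learning_rate = 0.1, split = sp, seed = 2)
  expect_equal(nrow(out3$results), 2)
  expect_true(out3$best$n_rounds %in% c(2L, 3L))
})
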