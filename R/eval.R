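# largest-remainder allocation of per-class counts at a fraction
allocate_counts <- function(n_by_class, fraction) {
  quota <- n_by_class * fraction
  base <- floor(quota)
  total <- round(sum(quota))
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)  # ties -> class order
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Stratified train / validation / test split
#'
#' Sets aside `test_fraction` of the samples for testing, then splits the
#' remainder into training and validation at `val_fraction` for validation.
#' Class frequencies are balanced across subsets by allocating each class
#' proportionally with largest-remainder rounding; the subsets are disjoint
#' and exhaustive.
#'
#' @param data Data frame with a label column.
#' @param label Label column (bare name or string).
#' @param test_fraction Fraction of all samples set aside for testing.
#' @param val_fraction Fraction of the non-test remainder used for
#'   validation.
#' @param seed Integer seed for the within-class shuffles.
#' @return List of integer row-index vectors `train`, `val`, `test`.
#' @examples
#' d <- iris_with_noise(seed = 1)
#' sp <- stratified_three_way_split(d, species, seed = 1)
#' lengths(sp)
#' @export
stratified_three_way_split <- function(data, label, test_fraction = 0.30,
                                       val_fraction = 0.20, seed = 1L) {
  label <- rlang::as_name(rlang::ensym(label))
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction > 0, val_fraction < 1)
  y <- factor(data[[label]])
  tab <- table(y)
  if (any(tab < 3L)) {
    stop("class(es) with fewer than 3 samples: ",
         paste(names(tab)[tab < 3L], collapse = ", "), call. = FALSE)
  }
  n_test <- allocate_counts(as.vector(tab), test_fraction)
  n_val <- allocate_counts(as.vector(tab) - n_test, val_fraction)
  train <- integer(0); val <- integer(0); test <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(tab)) {
      idx <- sample(which(as.integer(y) == ci))
      test <- c(test, idx[seq_len(n_test[ci])])
      val <- c(val, idx[n_test[ci] + seq_len(n_val[ci])])
      train <- c(train, idx[-seq_len(n_test[ci] + n_val[ci])])
    }
  })
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Multi-class classification metrics
#'
#' Accuracy plus precision, recall and F1 in class-support-weighted form
#' (the primary summary), with macro F1 and per-class rows alongside. A class
#' never predicted contributes precision 0.
#'
#' @param truth Factor or character vector of true labels.
#' @param estimate Predicted labels, same length.
#' @param class_list Ordered class labels; defaults to the union of levels.
#' @return Tibble with columns `metric`, `class` (`NA` for aggregate rows)
#'   and `value` (proportions in `[0, 1]`). Aggregate metrics: `accuracy`,
#'   `precision_weighted`, `recall_weighted`, `f1_weighted`, `f1_macro`;
#'   per-class: `precision`, `recall`, `f1`.
#' @examples
#' classification_report(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
#' @export
classification_report <- function(truth, estimate, class_list = NULL) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  if (is.null(class_list)) {
    class_list <- sort(unique(c(as.character(truth), as.character(estimate))))
  }
  unknown <- setdiff(unique(c(as.character(truth), as.character(estimate))),
                     class_list)
  if (length(unknown) > 0L) {
    stop("labels outside class_list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  truth <- factor(truth, levels = class_list)
  estimate <- factor(estimate, levels = class_list)
  cm <- table(truth, estimate)
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  agg <- tibble::tibble(
    metric = c("accuracy", "precision_weighted", "recall_weighted",
               "f1_weighted", "f1_macro"),
    class = NA_character_,
    value = unname(c(sum(tp) / sum(cm), sum(w * precision),
                     sum(w * recall), sum(w * f1),
                     mean(f1[support > 0]))))
  per <- tibble::tibble(
    metric = rep(c("precision", "recall", "f1"), each = length(class_list)),
    class = rep(class_list, times = 3L),
    value = unname(c(precision, recall, f1)))
  dplyr::bind_rows(agg, per)
}

pipeline_schema <- c(
  "algorithm", "dataset", "label", "seeds", "n_trees", "sample_fraction",
  "rounds", "learning_rate", "max_features", "min_samples_split", "theta",
  "network_file", "gene_map_file", "distance_file", "outdir",
  "test_fraction", "val_fraction", "impute_k", "collect_importance",
  "signed_loadings")

read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) trimws(paste(x[-1L], collapse = "="))),
                  trimws(vapply(kv, `[[`, character(1), 1L)))
}

resolve_pipeline_data <- function(config) {
  dataset <- config$dataset %||% "iris_with_noise"
  seed0 <- as.integer((config$seeds %||% 1L)[[1L]])
  if (dataset == "iris_with_noise") {
    list(data = iris_with_noise(seed = seed0), label = "species",
         distances = NULL)
  } else if (dataset == "iris_permuted") {
    list(data = permute_within_columns(iris_with_noise(seed = seed0),
                                       species, seed = seed0 + 1L),
         label = "species", distances = NULL)
  } else if (dataset == "synthetic_planted") {
    sim <- synthetic_planted(seed = seed0)
    list(data = sim$data, label = "class", distances = sim$distances)
  } else {
    if (!file.exists(dataset)) {
      stop("dataset file not found: ", dataset, call. = FALSE)
    }
    df <- readr::read_csv(dataset, show_col_types = FALSE)
    list(data = df, label = config$label %||% stop(
      "config key 'label' is required for file datasets", call. = FALSE),
      distances = NULL)
  }
}

#' Run a fit/evaluate/export experiment
#'
#' Orchestrates the full protocol for one algorithm over a list of seeds:
#' stratified three-way split, fit on the training set, metrics on the
#' validation and test sets, CLIFI collection, proximity matrix, and
#' delimited artifact files. The `impute_k` config key is accepted for
#' provenance only: input matrices must already be complete (impute upstream,
#' e.g. with a k-nearest-neighbour imputer).
#'
#' @param config Named list, or path to a flat `key=value` text file. Keys:
#'   `algorithm` (rf, lavaset, gbdt, lavaboost), `dataset` (iris_with_noise,
#'   iris_permuted, synthetic_planted, or a CSV path with a label column),
#'   `label`, `seeds` (vector or comma string), `n_trees`,
#'   `sample_fraction`, `rounds`, `learning_rate`, `max_features`,
#'   `min_samples_split`, `theta`, `network_file` + `gene_map_file` (STRING
#'   edges and feature-gene map) or `distance_file`, `test_fraction`,
#'   `val_fraction`, `signed_loadings`, `collect_importance`, `outdir`.
#'   Unknown keys raise a schema error listing the offenders.
#' @param outdir Output directory (overrides the config key).
#' @return Invisibly, a list with `metrics` (per-run and summary tibble) and
#'   `paths` of the written artifacts: `metrics.csv`, `clifi_records.csv`,
#'   `aclifi.csv`, `naclifi.csv`, `proximity.csv`, `run.log`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  bad <- setdiff(names(config), pipeline_schema)
  if (length(bad) > 0L) {
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  algorithm <- match.arg(tolower(config$algorithm %||% "rf"),
                         c("rf", "lavaset", "gbdt", "lavaboost"))
  seeds <- config$seeds %||% 1L
  if (is.character(seeds)) {
    seeds <- as.integer(strsplit(seeds, ",")[[1L]])
  }
  seeds <- as.integer(seeds)
  outdir <- outdir %||% config$outdir %||%
    stop("an output directory is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  src <- resolve_pipeline_data(config)
  data <- src$data
  label <- config$label %||% src$label
  lava <- algorithm %in% c("lavaset", "lavaboost")
  nb <- NULL
  if (lava) {
    D <- if (!is.null(config$distance_file)) {
      read_distance_matrix(config$distance_file)
    } else if (!is.null(config$network_file)) {
      edges <- parse_interaction_table(config$network_file)
      map <- readr::read_csv(config$gene_map_file, show_col_types = FALSE)
      build_feature_distance_matrix(edges, map)
    } else if (!is.null(src$distances)) {
      src$distances
    } else {
      # no interaction information: every feature is its own neighbourhood
      p <- length(setdiff(names(data), label))
      Dm <- matrix(Inf, p, p)
      diag(Dm) <- 0
      Dm
    }
    if (is.null(config$theta)) {
      stop("config key 'theta' is required for latent-variable algorithms",
           call. = FALSE)
    }
    nb <- neighbourhoods(D, as.numeric(config$theta))
  }

  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) writeLines(paste0(...), log_con)
  logf("algorithm=", algorithm, " dataset=", config$dataset %||% "default",
       " seeds=", paste(seeds, collapse = ","))

  per_run <- list()
  model <- NULL
  for (s in seeds) {
    sp <- stratified_three_way_split(
      data, !!rlang::sym(label),
      test_fraction = as.numeric(config$test_fraction %||% 0.30),
      val_fraction = as.numeric(config$val_fraction %||% 0.20), seed = s)
    train <- data[sp$train, ]
    model <- switch(algorithm,
      rf = , lavaset = clifi_forest(
        train, !!rlang::sym(label),
        n_trees = as.integer(config$n_trees %||% 150L),
        max_features = config$max_features %||% "sqrt",
        sample_fraction = as.numeric(config$sample_fraction %||% 0.8),
        min_samples_split = as.integer(config$min_samples_split %||% 2L),
        neighbourhoods = nb, seed = s),
      gbdt = , lavaboost = clifi_boost(
        train, !!rlang::sym(label),
        n_rounds = as.integer(config$rounds %||% 130L),
        learning_rate = as.numeric(config$learning_rate %||% 0.1),
        max_features = config$max_features %||% "sqrt",
        min_samples_split = as.integer(config$min_samples_split %||% 2L),
        neighbourhoods = nb, seed = s))
    for (subset in c("val", "test")) {
      eval_data <- data[sp[[subset]], ]
      pred <- predict(model, eval_data)
      rep_tbl <- classification_report(eval_data[[label]], pred$.pred_class,
                                       model$class_list)
      agg <- rep_tbl[is.na(rep_tbl$class), ]
      per_run[[paste(s, subset)]] <- tibble::tibble(
        seed = s, subset = subset, metric = agg$metric,
        value = 100 * agg$value)
    }
    logf("seed=", s, " fitted ", algorithm)
  }
  per_run <- dplyr::bind_rows(per_run)
  summary_tbl <- per_run |>
    dplyr::group_by(.data$subset, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  metrics <- dplyr::bind_rows(
    dplyr::mutate(per_run, row = "run", mean = .data$value, sd = NA_real_),
    dplyr::mutate(summary_tbl, row = "summary", seed = NA_integer_,
                  value = NA_real_))
  metrics <- metrics[c("row", "seed", "subset", "metric", "value",
                       "mean", "sd")]

  paths <- list(metrics = file.path(outdir, "metrics.csv"),
                log = log_path)
  readr::write_csv(metrics, paths$metrics)

  if (isTRUE(as.logical(config$collect_importance %||% TRUE))) {
    tab <- collect_clifi(model,
                         signed = isTRUE(as.logical(
                           config$signed_loadings %||% TRUE)))
    paths$clifi_records <- file.path(outdir, "clifi_records.csv")
    paths$aclifi <- file.path(outdir, "aclifi.csv")
    paths$naclifi <- file.path(outdir, "naclifi.csv")
    readr::write_csv(tab$records, paths$clifi_records)
    readr::write_csv(tibble::as_tibble(as.data.frame(tab$aclifi),
                                       rownames = "feature"), paths$aclifi)
    readr::write_csv(tibble::as_tibble(as.data.frame(tab$naclifi),
                                       rownames = "feature"), paths$naclifi)
  }
  prox <- proximity_matrix(model, data[setdiff(names(data), label)])
  paths$proximity <- file.path(outdir, "proximity.csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(prox)), paths$proximity)
  logf("artifacts written to ", outdir)
  invisible(list(metrics = metrics, paths = paths, model = model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search over ensemble hyperparameters
#'
#' Fits one model per grid point on the training subset and scores it on the
#' validation subset; the winner has the highest validation weighted F1, with
#' ties resolved towards the smaller model (fewer trees or rounds, then the
#' smaller learning rate). Forests are searched over `n_trees`; boosters over
#' `n_rounds` x `learning_rate`. Defaults cover trees 100-180 in steps of 10,
#' rounds 10-150 in steps of 10 and learning rates 0.1/0.2/0.3.
#'
#' @param data Data frame with a label column.
#' @param label Label column (bare name or string).
#' @param algorithm `"rf"`, `"lavaset"`, `"gbdt"` or `"lavaboost"`.
#' @param n_trees,n_rounds,learning_rate Numeric vectors defining the grid.
#' @param neighbourhoods Neighbourhood index for the latent-variable
#'   algorithms.
#' @param split A list of `train` / `val` indices (e.g. from
#'   [stratified_three_way_split()]); by default a split at the package's
#'   standard fractions is drawn with `seed`.
#' @param seed Integer seed used for the default split and all fits.
#' @param ... Further arguments passed to the fitting function.
#' @return List with `results` (one row per grid point with validation
#'   weighted F1) and `best` (the winning row).
#' @export
hyperparameter_search <- function(data, label,
                                  algorithm = c("rf", "lavaset", "gbdt",
                                                "lavaboost"),
                                  n_trees = seq(100L, 180L, by = 10L),
                                  n_rounds = seq(10L, 150L, by = 10L),
                                  learning_rate = c(0.1, 0.2, 0.3),
                                  neighbourhoods = NULL, split = NULL,
                                  seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  label <- rlang::as_name(rlang::ensym(label))
  if (is.null(split)) {
    split <- stratified_three_way_split(data, !!rlang::sym(label),
                                        seed = seed)
  }
  train <- data[split$train, ]
  val <- data[split$val, ]
  bagged <- algorithm %in% c("rf", "lavaset")
  grid <- if (bagged) {
    tibble::tibble(n_trees = sort(n_trees))
  } else {
    tidyr::expand_grid(n_rounds = sort(n_rounds),
                       learning_rate = sort(learning_rate))
  }
  score <- function(fit) {
    pred <- predict(fit, val)$.pred_class
    rep_tbl <- classification_report(val[[label]], pred, fit$class_list)
    rep_tbl$value[rep_tbl$metric == "f1_weighted"]
  }
  grid$f1_weighted <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- if (bagged) {
      clifi_forest(train, !!rlang::sym(label), n_trees = grid$n_trees[i],
                   neighbourhoods = neighbourhoods, seed = seed, ...)
    } else {
      clifi_boost(train, !!rlang::sym(label), n_rounds = grid$n_rounds[i],
                  learning_rate = grid$learning_rate[i],
                  neighbourhoods = neighbourhoods, seed = seed, ...)
    }
    score(fit)
  }, numeric(1))
  # highest validation F1; ties to the smaller model (grid is sorted)
  best <- grid[which.max(grid$f1_weighted), ]
  list(results = grid, best = best)
}
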