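# tree <-> plain list (JSON-safe) conversion
tree_to_list <- function(tree) {
  list(nodes = lapply(tree$nodes, function(n) {
    if (n$is_leaf) {
      list(id = n$id, is_leaf = TRUE, counts = n$counts, value = n$value,
           n = n$n)
    } else {
      list(id = n$id, is_leaf = FALSE, feature = n$feature,
           neighbourhood = n$neighbourhood, loadings = n$loadings,
           center = n$center, threshold = n$threshold, left = n$left,
           right = n$right, counts_parent = n$counts_parent,
           counts_left = n$counts_left, counts_right = n$counts_right,
           impurity_decrease = n$impurity_decrease)
    }
  }),
  root = tree$root, mode = tree$mode, root_counts = tree$root_counts,
  n_groups = tree$n_groups, train_leaf = tree$train_leaf, p = tree$p,
  class_list = tree$class_list, feature_names = tree$feature_names,
  error_label_values = tree$error_label_values,
  error_label_weights = if (!is.null(tree$error_label_weights))
    as.data.frame(tree$error_label_weights))
}

tree_from_list <- function(x) {
  nodes <- lapply(x$nodes, function(n) {
    n$is_leaf <- isTRUE(n$is_leaf)
    n
  })
  tr <- list(nodes = nodes, root = x$root, mode = x$mode,
             root_counts = as.numeric(x$root_counts),
             n_groups = x$n_groups, train_leaf = x$train_leaf, p = x$p,
             class_list = x$class_list, feature_names = x$feature_names,
             error_label_values = x$error_label_values)
  if (!is.null(x$error_label_weights)) {
    tr$error_label_weights <- as.matrix(x$error_label_weights)
  }
  structure(tr, class = "clifi_tree")
}

#' Save a fitted model as JSON
#'
#' Serialises a fitted forest or booster (trees with node ids,
#' neighbourhoods, loadings, centres, thresholds and class counts, plus the
#' ensemble bookkeeping) to a JSON file at full double precision, so that a
#' reloaded model reproduces predictions and CLIFI tables exactly.
#'
#' @param model A `clifi_forest` or `clifi_boost`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clifi_model <- function(model, path) {
  obj <- if (inherits(model, "clifi_forest")) {
    list(type = "forest",
         trees = lapply(model$trees, tree_to_list),
         per_tree_sample_indices = model$per_tree_sample_indices,
         class_list = model$class_list,
         feature_names = model$feature_names,
         n_samples = model$n_samples, params = model$params)
  } else if (inherits(model, "clifi_boost")) {
    list(type = "boost",
         trees = lapply(model$trees, function(rt) lapply(rt, tree_to_list)),
         class_list = model$class_list,
         feature_names = model$feature_names, n_samples = model$n_samples,
         learning_rate = model$learning_rate, n_rounds = model$n_rounds,
         train_accuracy = model$train_accuracy, p = model$p,
         params = model$params)
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [write_clifi_model()]
#'
#' @param path JSON file path.
#' @return The restored `clifi_forest` or `clifi_boost`.
#' @export
read_clifi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  fix_tree <- function(tl) {
    tl$nodes <- lapply(tl$nodes, function(n) {
      for (f in c("neighbourhood", "loadings", "center", "counts",
                  "counts_parent", "counts_left", "counts_right")) {
        if (!is.null(n[[f]])) n[[f]] <- as.numeric(unlist(n[[f]]))
      }
      n
    })
    for (f in c("root_counts", "train_leaf", "error_label_values")) {
      if (!is.null(tl[[f]])) tl[[f]] <- as.numeric(unlist(tl[[f]]))
    }
    if (!is.null(tl$error_label_weights)) {
      tl$error_label_weights <-
        do.call(cbind, lapply(tl$error_label_weights, unlist))
    }
    if (!is.null(tl$class_list)) tl$class_list <- unlist(tl$class_list)
    if (!is.null(tl$feature_names)) {
      tl$feature_names <- unlist(tl$feature_names)
    }
    tree_from_list(tl)
  }
  if (obj$type == "forest") {
    structure(list(
      trees = lapply(obj$trees, fix_tree),
      per_tree_sample_indices = lapply(obj$per_tree_sample_indices,
                                       function(v) as.integer(unlist(v))),
      class_list = unlist(obj$class_list),
      feature_names = unlist(obj$feature_names),
      n_samples = obj$n_samples, params = obj$params,
      neighbourhoods = NULL), class = "clifi_forest")
  } else {
    structure(list(
      trees = lapply(obj$trees, function(rt) lapply(rt, fix_tree)),
      class_list = unlist(obj$class_list),
      feature_names = unlist(obj$feature_names),
      n_samples = obj$n_samples, learning_rate = obj$learning_rate,
      n_rounds = obj$n_rounds,
      train_accuracy = as.numeric(unlist(obj$train_accuracy)),
      p = obj$p, params = obj$params,
      neighbourhoods = NULL), class = "clifi_boost")
  }
}

#' Export a CLIFI table to delimited files
#'
#' Writes the tidy split-level records and the aggregated/normalised
#' feature-by-class matrices as comma-separated files with headers.
#'
#' @param table A `clifi_table`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_clifi_table <- function(table, dir) {
  stopifnot(inherits(table, "clifi_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(records = file.path(dir, "clifi_records.csv"),
                aclifi = file.path(dir, "aclifi.csv"),
                naclifi = file.path(dir, "naclifi.csv"))
  readr::write_csv(table$records, paths$records)
  readr::write_csv(tibble::as_tibble(as.data.frame(table$aclifi),
                                     rownames = "feature"), paths$aclifi)
  readr::write_csv(tibble::as_tibble(as.data.frame(table$naclifi),
                                     rownames = "feature"), paths$naclifi)
  invisible(paths)
}
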