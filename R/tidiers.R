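#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

tree_stats <- function(tree) {
  is_leaf <- vapply(tree$nodes, `[[`, logical(1), "is_leaf")
  depth <- local({
    d <- function(id, lvl) {
      node <- tree$nodes[[id]]
      if (node$is_leaf) return(lvl)
      max(d(node$left, lvl + 1L), d(node$right, lvl + 1L))
    }
    d(tree$root, 0L)
  })
  c(n_nodes = length(tree$nodes), n_leaves = sum(is_leaf), depth = depth)
}

#' Tidy a bagged ensemble into per-tree statistics
#'
#' @param x A `clifi_forest`.
#' @param ... Unused.
#' @return Tibble with one row per tree: `tree`, `n_samples`, `n_nodes`,
#'   `n_leaves`, `depth`.
#' @method tidy clifi_forest
#' @export
tidy.clifi_forest <- function(x, ...) {
  st <- t(vapply(x$trees, tree_stats, numeric(3)))
  tibble::tibble(tree = seq_along(x$trees),
                 n_samples = lengths(x$per_tree_sample_indices),
                 n_nodes = as.integer(st[, "n_nodes"]),
                 n_leaves = as.integer(st[, "n_leaves"]),
                 depth = as.integer(st[, "depth"]))
}

#' One-row summary of a bagged ensemble
#'
#' @param x A `clifi_forest`.
#' @param ... Unused.
#' @return One-row tibble: `n_trees`, `n_features`, `n_classes`,
#'   `sample_fraction`, `lava`.
#' @method glance clifi_forest
#' @export
glance.clifi_forest <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees),
                 n_features = length(x$feature_names),
                 n_classes = length(x$class_list),
                 sample_fraction = x$params$sample_fraction,
                 lava = x$params$lava)
}

#' Tidy a boosted ensemble into per-round statistics
#'
#' @param x A `clifi_boost`.
#' @param ... Unused.
#' @return Tibble with one row per (round, class): `round`, `class`,
#'   `n_nodes`, `depth`, plus the training accuracy after that round.
#' @method tidy clifi_boost
#' @export
tidy.clifi_boost <- function(x, ...) {
  rows <- list()
  for (mr in seq_along(x$trees)) {
    for (k in seq_along(x$class_list)) {
      st <- tree_stats(x$trees[[mr]][[k]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        round = mr, class = x$class_list[k],
        n_nodes = as.integer(st["n_nodes"]),
        depth = as.integer(st["depth"]),
        train_accuracy = x$train_accuracy[mr])
    }
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a boosted ensemble
#'
#' @param x A `clifi_boost`.
#' @param ... Unused.
#' @return One-row tibble: `n_rounds`, `learning_rate`, `n_features`,
#'   `n_classes`, `lava`, `train_accuracy` (final).
#' @method glance clifi_boost
#' @export
glance.clifi_boost <- function(x, ...) {
  tibble::tibble(n_rounds = x$n_rounds,
                 learning_rate = x$learning_rate,
                 n_features = length(x$feature_names),
                 n_classes = length(x$class_list),
                 lava = x$params$lava,
                 train_accuracy = if (x$n_rounds > 0)
                   x$train_accuracy[x$n_rounds] else NA_real_)
}

#' Tidy a CLIFI table into its split-level records
#'
#' @param x A `clifi_table`.
#' @param ... Unused.
#' @return The records tibble: `tree_id`, `node_id`, `feature`, `class`,
#'   `value`.
#' @method tidy clifi_table
#' @export
tidy.clifi_table <- function(x, ...) {
  x$records
}

#' One-row summary of a CLIFI table
#'
#' @param x A `clifi_table`.
#' @param ... Unused.
#' @return One-row tibble: `n_records`, `n_features`, `n_classes`,
#'   `max_abs_aclifi`.
#' @method glance clifi_table
#' @export
glance.clifi_table <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$records),
                 n_features = length(x$feature_names),
                 n_classes = length(x$class_list),
                 max_abs_aclifi = max(abs(x$aclifi)))
}
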