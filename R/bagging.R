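#' Fit a bagged tree ensemble (random forest / LAVASET)
#'
#' Grows `n_trees` CART trees, each on an independent subsample of the data
#' (without replacement by default, `ceiling(sample_fraction * n)` samples per
#' tree). Without a neighbourhood index this is a random forest; with one, the
#' trees use latent-variable splits over each candidate feature's graph
#' neighbourhood (the LAVASET variant). Every split retains its per-class
#' sample counts and loadings so that CLIFI importances can be read off the
#' fitted model with [collect_clifi()].
#'
#' @param data Data frame of numeric features plus one label column.
#' @param label Label column (bare name or string).
#' @param n_trees Number of trees.
#' @param max_features Candidate features per split: `"sqrt"`, `"all"` or an
#'   integer.
#' @param sample_fraction Fraction of samples drawn per tree.
#' @param replace Draw the per-tree subsample with replacement (classic
#'   bootstrap) instead of without.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param neighbourhoods Optional neighbourhood index from [neighbourhoods()].
#' @param seed Master seed; per-tree seeds are derived from it by counter so
#'   results do not depend on evaluation order.
#' @return A `clifi_forest` object.
#' @examples
#' d <- iris_with_noise(seed = 1)
#' fit <- clifi_forest(d, species, n_trees = 10, seed = 1)
#' predict(fit, d)
#' @export
clifi_forest <- function(data, label, n_trees = 150L, max_features = "sqrt",
                         sample_fraction = 0.8, replace = FALSE,
                         min_samples_split = 2L, neighbourhoods = NULL,
                         seed = 1L) {
  ds <- as_dataset(data, !!rlang::ensym(label))
  n <- nrow(ds$X)
  p <- ncol(ds$X)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]", call. = FALSE)
  }
  nb <- check_neighbourhoods(neighbourhoods, p)
  m <- resolve_max_features(max_features, p)
  K <- nlevels(ds$y)
  n_sub <- ceiling(sample_fraction * n)
  tree_seeds <- derive_seeds(seed, n_trees)
  y_int <- as.integer(ds$y)

  trees <- vector("list", n_trees)
  sample_indices <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    withr::with_seed(tree_seeds[t], {
      idx <- sample.int(n, n_sub, replace = replace)
      tree <- grow_tree_impl(ds$X[idx, , drop = FALSE], y_int[idx],
                             "classification", y_int[idx], K, m,
                             as.integer(min_samples_split), nb)
    })
    tree$class_list <- levels(ds$y)
    tree$feature_names <- ds$feature_names
    trees[[t]] <- tree
    sample_indices[[t]] <- idx
  }

  structure(list(
    trees = trees, per_tree_sample_indices = sample_indices,
    class_list = levels(ds$y), feature_names = ds$feature_names,
    n_samples = n,
    params = list(n_trees = n_trees, max_features = max_features,
                  sample_fraction = sample_fraction, replace = replace,
                  min_samples_split = min_samples_split,
                  lava = !is.null(nb), seed = seed),
    neighbourhoods = nb
  ), class = "clifi_forest")
}

# per-tree vote matrix n x K
forest_votes <- function(object, X) {
  K <- length(object$class_list)
  votes <- matrix(0, nrow(X), K)
  for (tree in object$trees) {
    pred <- apply_tree_impl(tree, X)$value
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + 1
  }
  votes / length(object$trees)
}

#' Predict from a bagged ensemble
#'
#' Majority vote over the trees; ties are broken towards the class that comes
#' first in the model's class list.
#'
#' @param object A `clifi_forest`.
#' @param new_data Data frame or matrix of features.
#' @param ... Unused.
#' @return A tibble with `.pred_class` plus one vote-fraction column
#'   `.pred_<class>` per class (rows sum to 1).
#' @export
predict.clifi_forest <- function(object, new_data, ...) {
  X <- tree_feature_matrix(object$trees[[1L]], new_data)
  votes <- forest_votes(object, X)
  win <- apply(votes, 1L, which.max)
  out <- tibble::as_tibble(as.data.frame(votes))
  names(out) <- paste0(".pred_", object$class_list)
  dplyr::bind_cols(
    tibble::tibble(.pred_class = factor(object$class_list[win],
                                        levels = object$class_list)),
    out)
}

#' Leaf co-occurrence proximity matrix
#'
#' Entry (u, v) is the fraction of trees in which samples u and v land in the
#' same leaf. Symmetric, unit diagonal, entries in `[0, 1]`. Typically used as
#' input to an external embedding (e.g. UMAP) to visualise sample similarity
#' under the fitted model.
#'
#' @param model A fitted `clifi_forest` (or `clifi_boost`).
#' @param data Data frame of samples to compare (usually the training data;
#'   a label column is ignored).
#' @return An n x n numeric matrix.
#' @export
proximity_matrix <- function(model, data) {
  UseMethod("proximity_matrix")
}

proximity_from_trees <- function(trees, X) {
  n <- nrow(X)
  prox <- matrix(0, n, n)
  for (tree in trees) {
    leaf <- apply_tree_impl(tree, X)$leaf_ids
    prox <- prox + outer(leaf, leaf, "==")
  }
  prox <- prox / length(trees)
  rownames(prox) <- colnames(prox) <- rownames(X)
  prox
}

#' @export
proximity_matrix.clifi_forest <- function(model, data) {
  X <- tree_feature_matrix(model$trees[[1L]], data)
  proximity_from_trees(model$trees, X)
}

#' @export
print.clifi_forest <- function(x, ...) {
  cat("Bagged tree ensemble (", if (x$params$lava) "LAVASET" else "RF",
      "): ", length(x$trees), " trees, ", length(x$feature_names),
      " features, ", length(x$class_list), " classes\n", sep = "")
  invisible(x)
}
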