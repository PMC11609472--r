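#' Softmax class probabilities from raw scores
#'
#' Converts a matrix (or vector) of per-class additive scores F into class
#' probabilities `p_k = exp(F_k) / sum_l exp(F_l)`, computed with a row-wise
#' max shift for numerical stability.
#'
#' @param F_scores Numeric vector (one sample) or matrix (samples x classes).
#' @return Simplex vector or matrix of the same shape; rows sum to 1.
#' @examples
#' class_probabilities(c(1, 0))
#' @export
class_probabilities <- function(F_scores) {
  if (is.null(dim(F_scores))) {
    z <- exp(F_scores - max(F_scores))
    return(z / sum(z))
  }
  z <- exp(F_scores - apply(F_scores, 1L, max))
  z / rowSums(z)
}

#' Pseudo-residuals for one-vs-all boosting
#'
#' The negative gradient of the multinomial deviance under the softmax link:
#' one-hot class membership minus current class probabilities. Rows sum to
#' zero.
#'
#' @param one_hot_y Binary samples x classes membership matrix.
#' @param P Matrix of current class probabilities, same shape.
#' @return Numeric matrix of residuals.
#' @export
pseudo_residuals <- function(one_hot_y, P) {
  stopifnot(all(dim(one_hot_y) == dim(P)))
  one_hot_y - P
}

#' Leaf update value for a boosted regression tree
#'
#' Newton-step leaf value for the K-class one-vs-all deviance:
#' `gamma = ((K - 1) / K) * sum(r) / sum(|r| (1 - |r|))` over the residuals in
#' the leaf. A zero denominator yields 0 with a warning.
#'
#' @param residuals_in_leaf Numeric vector of pseudo-residuals in the leaf.
#' @param K Number of classes.
#' @return A single finite number.
#' @examples
#' leaf_gamma(c(2 / 3, -1 / 3), K = 3)
#' @export
leaf_gamma <- function(residuals_in_leaf, K) {
  r <- residuals_in_leaf
  if (length(r) == 0L) stop("empty leaf", call. = FALSE)
  den <- sum(abs(r) * (1 - abs(r)))
  if (den == 0) {
    if (any(r != 0)) warning("zero denominator in leaf update; using 0")
    return(0)
  }
  ((K - 1) / K) * sum(r) / den
}

#' Error labels of a pseudo-residual column
#'
#' Inside a boosted tree every sample's target is its pseudo-residual, so the
#' tree's "classes" are the distinct residual values ("error labels").
#' Residuals are rounded to 10 decimal places to guard against float jitter
#' before distinct values are identified. The returned weights give, for each
#' true class h, the share `S_hi` of its samples carrying each error label i
#' (rows of non-zero weights sum to 1); these reconcile error-label CLIFI
#' values back to true classes.
#'
#' @param residual_column Numeric vector of pseudo-residuals.
#' @param true_labels Factor of true class labels, same length.
#' @return List with `label_ids` (integer codes 1..L), `values` (the distinct
#'   rounded residuals, ascending) and `weights` (L x K matrix of `S_hi`,
#'   columns indexed by class).
#' @export
assign_error_labels <- function(residual_column, true_labels) {
  if (length(residual_column) == 0L) stop("empty residuals", call. = FALSE)
  true_labels <- factor(true_labels)
  rounded <- round(residual_column, 10L)
  values <- sort(unique(rounded))
  ids <- match(rounded, values)
  tab <- table(factor(ids, levels = seq_along(values)), true_labels)
  weights <- sweep(unclass(tab), 2L, colSums(tab), "/")
  weights[is.nan(weights)] <- 0
  dimnames(weights) <- list(NULL, levels(true_labels))
  list(label_ids = ids, values = values, weights = weights)
}

#' Fit a one-vs-all gradient-boosted tree ensemble (GBDT / LAVABOOST)
#'
#' Stagewise boosting of CART regression trees under the multinomial deviance
#' with a softmax link. The K-class problem is reduced to K per-class score
#' functions, all initialised to zero. Each round fits, per class, a
#' regression tree to the current pseudo-residuals (latent-variable splits if
#' a neighbourhood index is supplied), replaces leaf predictions by the
#' Newton leaf value ([leaf_gamma()]), and adds `learning_rate` times the tree
#' output to the scores. Split records keep per-error-label counts and each
#' tree keeps its class/error-label weight table so CLIFI importances can be
#' collected afterwards.
#'
#' @inheritParams clifi_forest
#' @param n_rounds Number of boosting rounds (M); `0` gives a constant model.
#' @param learning_rate Shrinkage applied to every leaf update.
#' @return A `clifi_boost` object. `$train_accuracy` traces training accuracy
#'   after each round.
#' @examples
#' d <- iris_with_noise(seed = 1)
#' fit <- clifi_boost(d, species, n_rounds = 3, seed = 1)
#' predict(fit, d)
#' @export
clifi_boost <- function(data, label, n_rounds = 130L, learning_rate = 0.1,
                        max_features = "sqrt", min_samples_split = 2L,
                        neighbourhoods = NULL, seed = 1L) {
  ds <- as_dataset(data, !!rlang::ensym(label))
  n <- nrow(ds$X)
  p <- ncol(ds$X)
  if (n_rounds < 0L) stop("n_rounds must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  nb <- check_neighbourhoods(neighbourhoods, p)
  m <- resolve_max_features(max_features, p)
  K <- nlevels(ds$y)
  y_int <- as.integer(ds$y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y_int)] <- 1

  tree_seeds <- matrix(derive_seeds(seed, max(1L, n_rounds) * K),
                       nrow = max(1L, n_rounds))
  F_scores <- matrix(0, n, K)
  trees <- vector("list", n_rounds)
  train_accuracy <- numeric(n_rounds)

  for (mr in seq_len(n_rounds)) {
    P <- class_probabilities(F_scores)
    R <- pseudo_residuals(Y, P)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- R[, k]
      el <- assign_error_labels(r, ds$y)
      tree <- withr::with_seed(tree_seeds[mr, k],
        grow_tree_impl(ds$X, r, "regression", el$label_ids,
                       length(el$values), m,
                       as.integer(min_samples_split), nb))
      # Newton leaf values
      leaves <- which(vapply(tree$nodes, `[[`, logical(1), "is_leaf"))
      for (id in leaves) {
        in_leaf <- tree$train_leaf == id
        tree$nodes[[id]]$value <- leaf_gamma(r[in_leaf], K)
      }
      F_scores[, k] <- F_scores[, k] + learning_rate *
        vapply(tree$nodes[tree$train_leaf], `[[`, numeric(1), "value")
      tree$error_label_values <- el$values
      tree$error_label_weights <- el$weights
      tree$feature_names <- ds$feature_names
      round_trees[[k]] <- tree
    }
    trees[[mr]] <- round_trees
    train_accuracy[mr] <-
      mean(max.col(F_scores, ties.method = "first") == y_int)
  }

  structure(list(
    trees = trees, class_list = levels(ds$y),
    feature_names = ds$feature_names, n_samples = n,
    learning_rate = learning_rate, n_rounds = n_rounds,
    train_accuracy = train_accuracy, F_train = F_scores, p = p,
    params = list(n_rounds = n_rounds, learning_rate = learning_rate,
                  max_features = max_features,
                  min_samples_split = min_samples_split,
                  lava = !is.null(nb), seed = seed),
    neighbourhoods = nb
  ), class = "clifi_boost")
}

boost_scores <- function(object, X) {
  K <- length(object$class_list)
  F_scores <- matrix(0, nrow(X), K)
  for (round_trees in object$trees) {
    for (k in seq_len(K)) {
      F_scores[, k] <- F_scores[, k] + object$learning_rate *
        apply_tree_impl(round_trees[[k]], X)$value
    }
  }
  F_scores
}

#' Predict from a boosted ensemble
#'
#' Accumulates the shrunken tree outputs from zero scores, applies the softmax
#' link, and predicts the arg-max class (ties towards the first class in the
#' class list).
#'
#' @param object A `clifi_boost`.
#' @param new_data Data frame or matrix of features.
#' @param ... Unused.
#' @return A tibble with `.pred_class` plus probability columns
#'   `.pred_<class>` (rows sum to 1).
#' @export
predict.clifi_boost <- function(object, new_data, ...) {
  X <- if (object$n_rounds > 0L) {
    tree_feature_matrix(object$trees[[1L]][[1L]], new_data)
  } else {
    Xr <- as.matrix(new_data[vapply(new_data, is.numeric, logical(1))])
    storage.mode(Xr) <- "double"
    Xr
  }
  P <- class_probabilities(boost_scores(object, X))
  win <- max.col(P, ties.method = "first")
  out <- tibble::as_tibble(as.data.frame(P))
  names(out) <- paste0(".pred_", object$class_list)
  dplyr::bind_cols(
    tibble::tibble(.pred_class = factor(object$class_list[win],
                                        levels = object$class_list)),
    out)
}

#' @export
proximity_matrix.clifi_boost <- function(model, data) {
  if (model$n_rounds == 0L) stop("model has no trees", call. = FALSE)
  X <- tree_feature_matrix(model$trees[[1L]][[1L]], data)
  proximity_from_trees(unlist(model$trees, recursive = FALSE), X)
}

#' @export
print.clifi_boost <- function(x, ...) {
  cat("Boosted tree ensemble (", if (x$params$lava) "LAVABOOST" else "GBDT",
      "): ", x$n_rounds, " rounds x ", length(x$class_list),
      " classes, learning rate ", x$learning_rate, "\n", sep = "")
  invisible(x)
}
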