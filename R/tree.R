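#' Gini impurity of a node
#'
#' Impurity of a set of class counts, `1 - sum((n_k / n)^2)`. Zero for a pure
#' node; at most `1 - 1/K` for `K` classes.
#'
#' @param class_counts Non-negative integer vector of per-class counts with at
#'   least one positive entry.
#' @return A single number in `[0, 1 - 1/K]`.
#' @examples
#' gini_impurity(c(5, 0))
#' gini_impurity(c(2, 2))
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class counts", call. = FALSE)
  n <- sum(class_counts)
  if (n == 0) stop("degenerate node: all class counts are zero", call. = FALSE)
  1 - sum((class_counts / n)^2)
}

#' Best axis-aligned split of one column
#'
#' Scans the midpoints of adjacent sorted distinct values of `column` and
#' returns the threshold maximising the impurity decrease: parent Gini minus
#' child-size-weighted Gini for classification, or the drop in total sum of
#' squared deviations for regression. Ties in gain are broken towards the
#' lowest threshold.
#'
#' @param column Numeric vector of feature values.
#' @param targets Class labels (classification) or numeric response
#'   (regression), same length as `column`.
#' @param mode `"classification"` or `"regression"`.
#' @return A list with `threshold`, `gain` and `n_left`, or `NULL` when no
#'   valid split exists (constant column).
#' @examples
#' find_best_split(c(1, 2, 3, 4), c("a", "a", "b", "b"), "classification")
#' @export
find_best_split <- function(column, targets,
                            mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  if (mode == "classification") {
    y <- factor(targets)
    best_split_cls(column, as.integer(y), nlevels(y))
  } else {
    best_split_reg(column, as.numeric(targets))
  }
}

# Classification split search; y integer codes in 1..K. Returns NULL sentinel
# for a constant column.
best_split_cls <- function(x, y, K) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cut <- which(xs[-n] < xs[-1L])           # boundaries between distinct values
  if (length(cut) == 0L) return(NULL)
  # prefix class counts at each cut
  left <- vapply(seq_len(K), function(k) cumsum(ys == k)[cut], numeric(length(cut)))
  left <- matrix(left, nrow = length(cut))
  tot <- tabulate(ys, nbins = K)
  right <- rep(tot, each = length(cut)) - left
  dim(right) <- dim(left)
  nl <- cut
  nr <- n - nl
  gini_l <- 1 - rowSums(left^2) / nl^2
  gini_r <- 1 - rowSums(right^2) / nr^2
  parent <- 1 - sum(tot^2) / n^2
  gain <- parent - (nl * gini_l + nr * gini_r) / n
  best <- which.max(gain)                  # first max -> lowest threshold
  list(threshold = (xs[cut[best]] + xs[cut[best] + 1L]) / 2,
       gain = gain[best], n_left = nl[best])
}

# Regression split search on total SSE decrease.
best_split_reg <- function(x, r) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  rs <- r[ord]
  cut <- which(xs[-n] < xs[-1L])
  if (length(cut) == 0L) return(NULL)
  cs1 <- cumsum(rs)[cut]
  cs2 <- cumsum(rs^2)[cut]
  s1 <- sum(rs)
  s2 <- sum(rs^2)
  nl <- cut
  nr <- n - nl
  sse_l <- cs2 - cs1^2 / nl
  sse_r <- (s2 - cs2) - (s1 - cs1)^2 / nr
  gain <- (s2 - s1^2 / n) - (sse_l + sse_r)
  best <- which.max(gain)
  if (gain[best] <= 0 && s2 - s1^2 / n == 0) return(NULL)  # constant response
  list(threshold = (xs[cut[best]] + xs[cut[best] + 1L]) / 2,
       gain = max(gain[best], 0), n_left = nl[best])
}

#' First-component latent scores of a feature neighbourhood
#'
#' The "LAVA" projection: columns of the node-local submatrix are centred
#' (not variance-scaled) and projected onto the first right singular vector of
#' the centred matrix. The singular vector's sign is fixed so that its
#' largest-magnitude element is positive, making the score direction
#' reproducible across decompositions.
#'
#' @param X_node Numeric matrix: samples in the node by neighbourhood features.
#' @param anchor Column index (within `X_node`) of the anchor feature; used to
#'   pick a fallback direction when the submatrix has zero variance.
#' @return List with `scores` (length `nrow(X_node)`), `loadings` (unit-norm,
#'   length `ncol(X_node)`) and `center` (column means).
#' @examples
#' lava_latent_scores(cbind(c(1, 2, 3), c(1, 2, 3)))
#' @export
lava_latent_scores <- function(X_node, anchor = 1L) {
  X_node <- as.matrix(X_node)
  m <- ncol(X_node)
  center <- colMeans(X_node)
  C <- sweep(X_node, 2L, center)
  if (all(C == 0)) {
    loadings <- numeric(m)
    loadings[anchor] <- 1
    return(list(scores = numeric(nrow(X_node)), loadings = loadings,
                center = center))
  }
  v1 <- tryCatch(svd(C, nu = 0L, nv = 1L)$v[, 1L],
                 error = function(e) {
                   eigen(crossprod(C), symmetric = TRUE)$vectors[, 1L]
                 })
  i <- which.max(abs(v1))
  if (v1[i] < 0) v1 <- -v1
  list(scores = drop(C %*% v1), loadings = v1, center = center)
}

# Grow one CART tree. Internal work-horse shared by forests and boosters.
#
# X, targets: training matrix and response (factor codes for classification,
#   numeric pseudo-residuals for regression).
# count_labels: integer codes (1..n_groups) whose per-node counts are recorded
#   in every split record -- true classes for classification trees, error
#   labels for boosted regression trees.
# neighbourhoods: NULL (plain axis-aligned splits) or list of sorted index
#   vectors per feature. Singleton neighbourhoods take the plain-split fast
#   path (loadings 1, center 0), which makes identity neighbourhoods
#   bit-identical to plain mode.
#
# Candidate anchors are drawn from the *current* RNG stream; callers seed it.
grow_tree_impl <- function(X, targets, mode, count_labels, n_groups,
                           max_features, min_samples_split = 2L,
                           neighbourhoods = NULL) {
  p <- ncol(X)
  n <- nrow(X)
  nodes <- vector("list", 64L)
  n_nodes <- 0L
  train_leaf <- integer(n)

  add_node <- function(node) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(nodes)) length(nodes) <<- 2L * n_nodes
    nodes[[n_nodes]] <<- node
    n_nodes
  }

  is_pure <- function(idx) {
    if (mode == "classification") {
      length(unique(targets[idx])) == 1L
    } else {
      all(targets[idx] == targets[idx[1L]])
    }
  }

  make_leaf <- function(idx, counts) {
    value <- if (mode == "classification") {
      which.max(counts)                    # first max = class-order tie-break
    } else {
      mean(targets[idx])
    }
    id <- add_node(list(id = NA_integer_, is_leaf = TRUE, counts = counts,
                        value = value, n = length(idx)))
    train_leaf[idx] <<- id
    id
  }

  grow <- function(idx) {
    counts <- tabulate(count_labels[idx], nbins = n_groups)
    if (length(idx) < min_samples_split || is_pure(idx)) {
      return(make_leaf(idx, counts))
    }
    cand <- sample.int(p, max_features)
    best <- NULL
    for (j in cand) {
      nb <- if (is.null(neighbourhoods)) j else neighbourhoods[[j]]
      if (length(nb) == 1L) {
        col <- X[idx, nb]
        loadings <- 1
        center <- 0
      } else {
        ls <- lava_latent_scores(X[idx, nb, drop = FALSE],
                                 anchor = match(j, nb))
        col <- ls$scores
        loadings <- ls$loadings
        center <- ls$center
      }
      sp <- if (mode == "classification") {
        best_split_cls(col, targets[idx], n_groups_cls)
      } else {
        best_split_reg(col, targets[idx])
      }
      if (is.null(sp)) next
      better <- is.null(best) ||
        sp$gain > best$gain + 1e-12 ||
        (abs(sp$gain - best$gain) <= 1e-12 &&
           (j < best$feature ||
              (j == best$feature && sp$threshold < best$threshold)))
      if (better) {
        best <- list(feature = j, neighbourhood = nb, loadings = loadings,
                     center = center, threshold = sp$threshold,
                     gain = sp$gain, col = col)
      }
    }
    if (is.null(best)) return(make_leaf(idx, counts))
    go_left <- best$col <= best$threshold
    li <- idx[go_left]
    ri <- idx[!go_left]
    if (length(li) == 0L || length(ri) == 0L) return(make_leaf(idx, counts))
    id <- add_node(list(id = NA_integer_, is_leaf = FALSE))
    left_id <- grow(li)
    right_id <- grow(ri)
    nodes[[id]] <<- list(
      id = id, is_leaf = FALSE,
      feature = best$feature, neighbourhood = best$neighbourhood,
      loadings = best$loadings, center = best$center,
      threshold = best$threshold,
      left = left_id, right = right_id,
      counts_parent = counts,
      counts_left = tabulate(count_labels[li], nbins = n_groups),
      counts_right = tabulate(count_labels[ri], nbins = n_groups),
      impurity_decrease = best$gain)
    id
  }

  # classification splits score the count groups themselves
  n_groups_cls <- n_groups
  root <- grow(seq_len(n))
  nodes <- nodes[seq_len(n_nodes)]
  for (i in seq_along(nodes)) nodes[[i]]$id <- i
  structure(list(nodes = nodes, root = root, mode = mode,
                 root_counts = tabulate(count_labels, nbins = n_groups),
                 n_groups = n_groups, train_leaf = train_leaf,
                 p = p),
            class = "clifi_tree")
}

#' Grow a single decision tree
#'
#' Fits one CART tree on a data frame, optionally with latent-variable
#' ("LAVA") splits: each candidate feature is replaced by the first
#' principal-component score of itself and its graph neighbours, computed on
#' the samples present at the node.
#'
#' @param data Data frame of numeric features plus one label column.
#' @param label Label column (bare name or string).
#' @param max_features `"sqrt"`, `"all"`, or an integer number of candidate
#'   features per split.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param neighbourhoods Optional list (one sorted integer vector per feature)
#'   from [neighbourhoods()]; `NULL` for plain axis-aligned splits.
#' @param seed Integer seed for the per-node candidate draws.
#' @return A `clifi_tree` object.
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4), cls = c("a", "a", "b", "b"))
#' tr <- grow_tree(d, cls, max_features = "all", seed = 1)
#' @export
grow_tree <- function(data, label, max_features = "all",
                      min_samples_split = 2L, neighbourhoods = NULL,
                      seed = 1L) {
  ds <- as_dataset(data, !!rlang::ensym(label))
  nb <- check_neighbourhoods(neighbourhoods, ncol(ds$X))
  m <- resolve_max_features(max_features, ncol(ds$X))
  tree <- withr::with_seed(as.integer(seed),
    grow_tree_impl(ds$X, as.integer(ds$y), "classification",
                   as.integer(ds$y), nlevels(ds$y), m,
                   as.integer(min_samples_split), nb))
  tree$class_list <- levels(ds$y)
  tree$feature_names <- ds$feature_names
  tree
}

# Route rows of X through a tree; returns leaf node ids and predictions
# (majority-class index for classification, leaf value for regression).
apply_tree_impl <- function(tree, X) {
  n <- nrow(X)
  leaf <- integer(n)
  route <- function(id, idx) {
    node <- tree$nodes[[id]]
    if (node$is_leaf) {
      leaf[idx] <<- id
      return(invisible())
    }
    nb <- node$neighbourhood
    z <- if (length(nb) == 1L && node$center[1L] == 0 &&
             node$loadings[1L] == 1) {
      X[idx, nb]
    } else {
      drop(sweep(X[idx, nb, drop = FALSE], 2L, node$center) %*% node$loadings)
    }
    go_left <- z <= node$threshold
    if (any(go_left)) route(node$left, idx[go_left])
    if (any(!go_left)) route(node$right, idx[!go_left])
  }
  route(tree$root, seq_len(n))
  value <- vapply(tree$nodes[leaf], `[[`, numeric(1), "value")
  list(leaf_ids = leaf, value = value)
}

#' Apply a tree to new samples
#'
#' Routes each row of a feature matrix through a fitted tree; at latent-split
#' nodes the stored centre and loadings are applied before the threshold
#' comparison.
#'
#' @param tree A `clifi_tree`.
#' @param new_data Data frame or matrix whose columns match the training
#'   features (a label column, if present, is ignored).
#' @return A tibble with `leaf_id` and `.pred_class` (or `.pred` for
#'   regression trees).
#' @export
apply_tree <- function(tree, new_data) {
  X <- tree_feature_matrix(tree, new_data)
  out <- apply_tree_impl(tree, X)
  if (tree$mode == "classification" && !is.null(tree$class_list)) {
    tibble::tibble(leaf_id = out$leaf_ids,
                   .pred_class = factor(tree$class_list[out$value],
                                        levels = tree$class_list))
  } else {
    tibble::tibble(leaf_id = out$leaf_ids, .pred = out$value)
  }
}

tree_feature_matrix <- function(tree, new_data) {
  X <- if (is.matrix(new_data)) new_data else {
    cols <- if (!is.null(tree$feature_names) &&
                all(tree$feature_names %in% names(new_data))) {
      tree$feature_names
    } else {
      names(new_data)[vapply(new_data, is.numeric, logical(1))]
    }
    as.matrix(new_data[cols])
  }
  if (ncol(X) != tree$p) {
    stop("new data has ", ncol(X), " feature columns; tree expects ", tree$p,
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}
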