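#' G-test goodness-of-fit statistic
#'
#' Likelihood-ratio statistic `G = 2 * sum_i O_i * ln(O_i / E_i)` over
#' categories with positive observed counts (zero-count categories are
#' skipped). Zero when observed equals expected.
#'
#' @param observed,expected Non-negative numeric vectors of per-category
#'   counts; `expected` must be positive wherever `observed` is.
#' @return The statistic, a single number.
#' @examples
#' g_test(c(15, 5), c(10, 10))
#' @export
g_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(observed < 0) || any(expected < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(expected) <= 0) stop("expected counts sum to zero", call. = FALSE)
  keep <- observed > 0
  if (any(expected[keep] == 0)) {
    stop("observed > 0 with expected = 0", call. = FALSE)
  }
  2 * sum(observed[keep] * log(observed[keep] / expected[keep]))
}

#' Partial G-test term of one child node
#'
#' The contribution `2 c ln(2c / P)` of a child holding `c` of the parent's
#' `P` samples of a class, i.e. the G-test term with expected count `P / 2`.
#' Zero-count children contribute 0 (the term is dropped). Vectorised.
#'
#' @param child_count Non-negative counts in the child.
#' @param parent_count Positive counts in the parent.
#' @return Numeric vector of partial statistics.
#' @examples
#' partial_g(3, 4)
#' @export
partial_g <- function(child_count, parent_count) {
  if (any(parent_count <= 0)) stop("parent count must be > 0", call. = FALSE)
  if (any(child_count < 0) || any(child_count > parent_count)) {
    stop("child count must lie in [0, parent]", call. = FALSE)
  }
  out <- numeric(length(child_count))
  pos <- child_count > 0
  out[pos] <- 2 * child_count[pos] *
    log(2 * child_count[pos] / parent_count[pos])
  out
}

#' Per-class directional importance of one split (CLIFI)
#'
#' The class-based integrated directional feature importance of a single
#' split, for one class with `left + right = parent` samples at the node and
#' `ancestor` samples of that class at the tree's root:
#'
#' `CLIFI = (M1 + M2) / (2 * ancestor * ln 2) * sign(M2 - M1)`
#'
#' where `M1, M2` are the [partial_g()] terms of the left and right child. The
#' magnitude is the combined G-test normalised by the perfect-split value
#' `2 * parent * ln 2` and scaled by `parent / ancestor`, so it lies in
#' `[0, parent / ancestor] <= 1`; the sign is positive when the class
#' concentrates in the right (higher-valued) child. A perfectly balanced
#' split scores exactly 0; a root split sending the whole class one way
#' scores exactly +1 or -1. Classes absent from the node (`parent = 0`)
#' score 0. Vectorised over classes.
#'
#' @param left,right Per-class counts in the left and right child.
#' @param parent Per-class counts at the node; must equal `left + right`.
#' @param ancestor Per-class counts at the tree's root; positive wherever
#'   `parent > 0`.
#' @return Numeric vector of values in `[-1, 1]`.
#' @examples
#' clifi_for_split(left = 0, right = 8, parent = 8, ancestor = 8)
#' clifi_for_split(left = 1, right = 3, parent = 4, ancestor = 8)
#' @export
clifi_for_split <- function(left, right, parent = left + right, ancestor) {
  ln <- max(length(left), length(right), length(parent), length(ancestor))
  left <- rep_len(left, ln); right <- rep_len(right, ln)
  parent <- rep_len(parent, ln); ancestor <- rep_len(ancestor, ln)
  if (any(left + right != parent)) {
    stop("left + right must equal parent for every class", call. = FALSE)
  }
  out <- numeric(ln)
  act <- parent > 0
  if (any(act & (ancestor <= 0))) {
    stop("ancestor count must be > 0 for scored classes", call. = FALSE)
  }
  if (any(parent > ancestor)) {
    stop("parent count cannot exceed ancestor count", call. = FALSE)
  }
  if (!any(act)) return(out)
  m1 <- partial_g(left[act], parent[act])
  m2 <- partial_g(right[act], parent[act])
  out[act] <- (m1 + m2) / (2 * ancestor[act] * log(2)) * sign(m2 - m1)
  out
}

#' Distribute a latent split's importance to original features
#'
#' Under a latent-variable split the importance belongs to the whole
#' neighbourhood; it is shared among the original features proportionally to
#' the absolute loadings (normalised to sum 1). In the default signed mode
#' the contribution of a feature with a negative loading has its sign
#' flipped, keeping directionality congruent with the raw feature values;
#' with `signed = FALSE` all features inherit the split's sign.
#'
#' @param split_value The split's importance value.
#' @param loadings Numeric loading vector over the neighbourhood (non-zero).
#' @param signed Flip each contribution's sign with its loading's sign.
#' @return Numeric vector of per-feature contributions whose absolute values
#'   sum to `|split_value|`.
#' @examples
#' distribute_to_original_features(0.7, c(0.8, -0.6))
#' @export
distribute_to_original_features <- function(split_value, loadings,
                                            signed = TRUE) {
  s <- sum(abs(loadings))
  if (s == 0) stop("all-zero loadings", call. = FALSE)
  w <- abs(loadings) / s
  if (signed) split_value * w * sign(loadings) else split_value * w
}

#' Reconcile error-label importances to a true class
#'
#' Boosted trees score error labels rather than true classes; the class-level
#' value is the weighted sum of the per-label values, each weighted by the
#' share `S_hi` of class h's samples carrying label i.
#'
#' @param per_label_values Numeric vector of per-error-label values.
#' @param weights Numeric vector of `S_hi` weights, same length, summing to 1
#'   over the labels present in the class.
#' @return The class-level value, bounded by `max(abs(per_label_values))`.
#' @examples
#' clifi_boosting_rescale(c(0.5, -0.5), c(0.6, 0.4))
#' @export
clifi_boosting_rescale <- function(per_label_values, weights) {
  if (length(per_label_values) != length(weights)) {
    stop("values and weights must align", call. = FALSE)
  }
  sum(weights * per_label_values)
}

# --- collection over fitted models ----------------------------------------

# per-tree count matrices for internal nodes
tree_internal_counts <- function(tree) {
  internal <- which(!vapply(tree$nodes, `[[`, logical(1), "is_leaf"))
  if (length(internal) == 0L) return(NULL)
  list(
    node_id = internal,
    CL = do.call(rbind, lapply(tree$nodes[internal], `[[`, "counts_left")),
    CR = do.call(rbind, lapply(tree$nodes[internal], `[[`, "counts_right")),
    CP = do.call(rbind, lapply(tree$nodes[internal], `[[`, "counts_parent"))
  )
}

# CLIFI matrix (internal nodes x groups) for one tree; groups = classes or
# error labels depending on what the tree counted.
tree_clifi_matrix <- function(tree) {
  tc <- tree_internal_counts(tree)
  if (is.null(tc)) return(NULL)
  A <- tree$root_counts
  V <- matrix(0, length(tc$node_id), tree$n_groups)
  for (g in seq_len(tree$n_groups)) {
    V[, g] <- clifi_for_split(tc$CL[, g], tc$CR[, g], tc$CP[, g],
                              rep(A[g], length(tc$node_id)))
  }
  list(node_id = tc$node_id, V = V, P = tc$CP)
}

# expand per-node class values into per-feature records via loadings
expand_records <- function(tree, tree_id, V, P, node_id, class_names,
                           signed = TRUE, keep = NULL) {
  recs <- vector("list", length(node_id))
  for (i in seq_along(node_id)) {
    node <- tree$nodes[[node_id[i]]]
    w <- distribute_to_original_features(1, node$loadings, signed = signed)
    cls <- if (is.null(keep)) which(V[i, ] != 0 | P[i, ] > 0) else
      which(keep[i, ])
    if (length(cls) == 0L) next
    nf <- length(node$neighbourhood)
    recs[[i]] <- tibble::tibble(
      node_id = node_id[i],
      feature_index = rep(node$neighbourhood, times = length(cls)),
      class = rep(class_names[cls], each = nf),
      value = as.vector(outer(w, V[i, cls])))
  }
  recs <- dplyr::bind_rows(recs)
  if (nrow(recs) == 0L) return(recs)
  recs$tree_id <- tree_id
  recs
}

#' Collect CLIFI records from a fitted model
#'
#' Reads the per-split class counts retained during training and computes one
#' directional importance record per internal node, scored class and
#' contributing original feature. Bagged models score true classes directly;
#' boosted models score error labels and reconcile them to true classes by
#' the per-tree weight tables. Records are then aggregated per
#' (feature, class) into the aCLIFI matrix and normalised by the largest
#' absolute entry into the naCLIFI matrix.
#'
#' @param model A fitted `clifi_forest` or `clifi_boost`.
#' @param signed Sign latent-split contributions by their loading signs
#'   (default) or keep the split's sign for all neighbours.
#' @return A `clifi_table`: list with `records` (tibble of `tree_id`,
#'   `node_id`, `feature`, `class`, `value`), `aclifi` and `naclifi`
#'   (features x classes matrices), `feature_names` and `class_list`.
#' @examples
#' d <- iris_with_noise(seed = 1)
#' fit <- clifi_forest(d, species, n_trees = 5, seed = 1)
#' tab <- collect_clifi(fit)
#' head(tab$records)
#' @export
collect_clifi <- function(model, signed = TRUE) {
  UseMethod("collect_clifi")
}

#' @export
collect_clifi.clifi_forest <- function(model, signed = TRUE) {
  recs <- vector("list", length(model$trees))
  for (t in seq_along(model$trees)) {
    tree <- model$trees[[t]]
    cm <- tree_clifi_matrix(tree)
    if (is.null(cm)) next
    keep <- cm$P > 0
    recs[[t]] <- expand_records(tree, t, cm$V, cm$P, cm$node_id,
                                model$class_list, signed = signed,
                                keep = keep)
  }
  finalize_clifi_table(dplyr::bind_rows(recs), model$feature_names,
                       model$class_list)
}

#' @export
collect_clifi.clifi_boost <- function(model, signed = TRUE) {
  if (model$n_rounds == 0L) {
    stop("model has no trees to collect from", call. = FALSE)
  }
  K <- length(model$class_list)
  recs <- list()
  t_id <- 0L
  for (mr in seq_along(model$trees)) {
    for (k in seq_len(K)) {
      t_id <- t_id + 1L
      tree <- model$trees[[mr]][[k]]
      cm <- tree_clifi_matrix(tree)
      if (is.null(cm)) next
      # reconcile error labels -> true classes: V_classes = V_labels %*% S
      S <- tree$error_label_weights
      Vc <- cm$V %*% S
      keep <- (cm$P %*% (S > 0)) > 0       # class has samples under the node
      recs[[t_id]] <- expand_records(tree, t_id, Vc, NULL, cm$node_id,
                                     model$class_list, signed = signed,
                                     keep = keep)
    }
  }
  finalize_clifi_table(dplyr::bind_rows(recs), model$feature_names,
                       model$class_list)
}

#' Construct a CLIFI table from a records tibble
#'
#' Builds a `clifi_table` from user-supplied importance records (for example
#' per-replicate aggregated values from repeated fits), aggregating and
#' normalising them like [collect_clifi()] does.
#'
#' @param records Tibble with columns `feature`, `class`, `value` (optional
#'   `tree_id`, `node_id` are kept if present).
#' @param feature_names,class_list Orderings for the aggregated matrices;
#'   default to the values present in `records`.
#' @return A `clifi_table`.
#' @export
new_clifi_table <- function(records,
                            feature_names = unique(records$feature),
                            class_list = unique(records$class)) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("feature", "class", "value") %in% names(records)))
  if (!"tree_id" %in% names(records)) records$tree_id <- NA_integer_
  if (!"node_id" %in% names(records)) records$node_id <- NA_integer_
  records <- records[c("tree_id", "node_id", "feature", "class", "value")]
  tab <- structure(list(records = records, feature_names = feature_names,
                        class_list = class_list, aclifi = NULL,
                        naclifi = NULL),
                   class = "clifi_table")
  aggregate_and_normalize(tab)
}

finalize_clifi_table <- function(records, feature_names, class_list) {
  if (nrow(records) > 0L) {
    records$feature <- feature_names[records$feature_index]
    records <- records[c("tree_id", "node_id", "feature", "class", "value")]
  } else {
    records <- tibble::tibble(tree_id = integer(), node_id = integer(),
                              feature = character(), class = character(),
                              value = numeric())
  }
  tab <- structure(list(records = records, feature_names = feature_names,
                        class_list = class_list, aclifi = NULL,
                        naclifi = NULL),
                   class = "clifi_table")
  aggregate_and_normalize(tab)
}

#' Aggregate and normalise a CLIFI table
#'
#' Sums records per (feature, class) into the aCLIFI matrix and divides by
#' the largest absolute entry to obtain naCLIFI, which allows comparison
#' between models. An all-zero table normalises to all zeros with a warning.
#'
#' @param table A `clifi_table`.
#' @return The table with `aclifi` and `naclifi` filled in.
#' @export
aggregate_and_normalize <- function(table) {
  stopifnot(inherits(table, "clifi_table"))
  p <- length(table$feature_names)
  K <- length(table$class_list)
  acl <- matrix(0, p, K,
                dimnames = list(table$feature_names, table$class_list))
  if (nrow(table$records) > 0L) {
    sums <- tapply(table$records$value,
                   list(factor(table$records$feature,
                               levels = table$feature_names),
                        factor(table$records$class,
                               levels = table$class_list)),
                   sum, default = 0)
    acl[] <- sums
  }
  mx <- max(abs(acl))
  if (mx == 0) {
    if (nrow(table$records) > 0L) warning("all aggregated values are zero")
    nacl <- acl
  } else {
    nacl <- acl / mx
  }
  table$aclifi <- acl
  table$naclifi <- nacl
  table
}

#' Top features of a class by aggregated importance
#'
#' For the positive direction, keeps features whose aggregated value exceeds
#' the mean of the positive aggregated values, ranks them descending, and
#' truncates to `k`; the negative direction is symmetric (below the mean of
#' the negative values, ranked ascending).
#'
#' @param table A `clifi_table` with aggregated matrices.
#' @param class Class name.
#' @param k Maximum number of features returned.
#' @param direction `"positive"` or `"negative"`.
#' @return Tibble with `feature`, `aclifi` and `rank`; empty when no feature
#'   passes the mean filter.
#' @export
select_top_features <- function(table, class, k = 10L,
                                direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "clifi_table"))
  if (!class %in% table$class_list) {
    stop("unknown class '", class, "'", call. = FALSE)
  }
  vals <- table$aclifi[, class]
  if (direction == "positive") {
    pos <- vals[vals > 0]
    sel <- if (length(pos) == 0L) character() else
      names(vals)[vals > mean(pos)]
    sel <- sel[order(vals[sel], decreasing = TRUE)]
  } else {
    neg <- vals[vals < 0]
    sel <- if (length(neg) == 0L) character() else
      names(vals)[vals < mean(neg)]
    sel <- sel[order(vals[sel])]
  }
  sel <- utils::head(sel, k)
  tibble::tibble(feature = sel, aclifi = unname(vals[sel]),
                 rank = seq_along(sel))
}

#' Rank tests for class differences in CLIFI values
#'
#' Per feature, a Kruskal-Wallis omnibus test of whether the split-level
#' CLIFI records differ between classes; features whose BH-adjusted omnibus
#' p-value passes `alpha` are followed up with pairwise Wilcoxon rank-sum
#' tests. All p-values are Benjamini-Hochberg adjusted (omnibus across
#' features; pairwise across all pairs jointly). Features with fewer than two
#' classes holding at least `min_records` records are skipped with a message.
#'
#' @param table A `clifi_table`.
#' @param alpha Significance level applied to adjusted omnibus p-values.
#' @param min_records Minimum records per class for a class to count.
#' @return Tibble with `feature`, `test` (`"kruskal"` or `"wilcoxon"`),
#'   `class_a`, `class_b` (NA for omnibus rows), `p_value` and `p_adj`.
#' @export
class_difference_tests <- function(table, alpha = 0.05, min_records = 2L) {
  stopifnot(inherits(table, "clifi_table"))
  recs <- table$records
  omni <- list()
  for (f in unique(recs$feature)) {
    sub <- recs[recs$feature == f, ]
    tab <- table(sub$class)
    ok <- names(tab)[tab >= min_records]
    if (length(ok) < 2L) {
      message("skipping feature '", f, "': fewer than 2 classes with >= ",
              min_records, " records")
      next
    }
    sub <- sub[sub$class %in% ok, ]
    kw <- stats::kruskal.test(sub$value, factor(sub$class))
    omni[[f]] <- tibble::tibble(feature = f, test = "kruskal",
                                class_a = NA_character_,
                                class_b = NA_character_,
                                p_value = unname(kw$p.value))
  }
  omni <- dplyr::bind_rows(omni)
  if (nrow(omni) == 0L) {
    return(tibble::tibble(feature = character(), test = character(),
                          class_a = character(), class_b = character(),
                          p_value = numeric(), p_adj = numeric()))
  }
  omni$p_adj <- stats::p.adjust(omni$p_value, method = "BH")
  pair <- list()
  for (f in omni$feature[omni$p_adj < alpha & !is.na(omni$p_adj)]) {
    sub <- recs[recs$feature == f, ]
    tab <- table(sub$class)
    ok <- names(tab)[tab >= min_records]
    for (i in seq_along(ok)) {
      for (j in seq_len(i - 1L)) {
        a <- ok[j]; b <- ok[i]
        wt <- suppressWarnings(stats::wilcox.test(
          sub$value[sub$class == a], sub$value[sub$class == b],
          exact = FALSE))
        pair[[paste(f, a, b)]] <- tibble::tibble(
          feature = f, test = "wilcoxon", class_a = a, class_b = b,
          p_value = unname(wt$p.value))
      }
    }
  }
  pair <- dplyr::bind_rows(pair)
  if (nrow(pair) > 0L) pair$p_adj <- stats::p.adjust(pair$p_value, "BH")
  dplyr::bind_rows(omni, pair)
}

#' @export
print.clifi_table <- function(x, ...) {
  cat("CLIFI table: ", nrow(x$records), " split records over ",
      length(x$feature_names), " features x ", length(x$class_list),
      " classes (max |aCLIFI| = ",
      format(max(abs(x$aclifi)), digits = 4), ")\n", sep = "")
  invisible(x)
}
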