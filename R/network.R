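#' Parse a STRING-style interaction table
#'
#' Reads a tab- or comma-separated table of pairwise interactions (two
#' identifiers and a combined confidence score per row), keeps edges at or
#' above the confidence threshold, and deduplicates undirected pairs.
#' Scores on the STRING 0-1000 scale are divided by 1000. A header row is
#' detected by a non-numeric score field; malformed rows are skipped with a
#' message.
#'
#' @param source File path, character vector of lines, or a data frame with
#'   at least three columns (id_a, id_b, score).
#' @param confidence_threshold Minimum confidence kept, on the 0-1 scale.
#' @return Tibble with `id_a`, `id_b`, `confidence` (one row per undirected
#'   pair, `id_a < id_b` lexicographically).
#' @examples
#' parse_interaction_table(c("A\tB\t850", "B\tA\t850", "A\tC\t400"))
#' @export
parse_interaction_table <- function(source, confidence_threshold = 0.7) {
  if (is.data.frame(source)) {
    df <- source[, 1:3]
    names(df) <- c("id_a", "id_b", "score")
    df$score <- suppressWarnings(as.numeric(df$score))
  } else {
    lines <- if (length(source) == 1L && file.exists(source)) {
      readLines(source)
    } else {
      source
    }
    lines <- lines[nzchar(trimws(lines))]
    sep <- if (any(grepl("\t", lines))) "\t" else ","
    parts <- strsplit(lines, sep, fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad)) {
      message("skipping ", sum(bad), " malformed row(s)")
      parts <- parts[!bad]
    }
    df <- tibble::tibble(
      id_a = vapply(parts, `[[`, character(1), 1L),
      id_b = vapply(parts, `[[`, character(1), 2L),
      score = suppressWarnings(
        as.numeric(vapply(parts, `[[`, character(1), 3L))))
    if (nrow(df) > 0L && is.na(df$score[1L])) df <- df[-1L, ]  # header row
  }
  drop_na <- is.na(df$score)
  if (any(drop_na)) {
    message("skipping ", sum(drop_na), " row(s) with non-numeric scores")
    df <- df[!drop_na, ]
  }
  df$id_a <- trimws(df$id_a)
  df$id_b <- trimws(df$id_b)
  if (nrow(df) > 0L && max(df$score) > 1) df$score <- df$score / 1000
  df <- df[df$score >= confidence_threshold & df$id_a != df$id_b, ]
  if (nrow(df) == 0L) {
    warning("no interactions pass the confidence threshold")
    return(tibble::tibble(id_a = character(), id_b = character(),
                          confidence = numeric()))
  }
  a <- pmin(df$id_a, df$id_b)
  b <- pmax(df$id_a, df$id_b)
  out <- tibble::tibble(id_a = a, id_b = b, confidence = df$score)
  out <- out[order(out$id_a, out$id_b, -out$confidence), ]
  out[!duplicated(out[c("id_a", "id_b")]), ]
}

#' Hop-distance matrix between features over an interaction graph
#'
#' Builds the feature-level adjacency implied by an interaction edge table
#' and a feature-to-gene map: two features are adjacent when they map to a
#' shared gene or when their genes interact. Distances are shortest-path hop
#' counts over this adjacency; the diagonal is 0 and unreachable pairs are
#' `Inf`. Features with no gene mapping become isolated (self-only) with a
#' message.
#'
#' @param edges Tibble from [parse_interaction_table()] (columns `id_a`,
#'   `id_b`).
#' @param feature_to_gene Data frame with columns `feature` and `gene`
#'   (a feature may map to several genes). Matching is exact after whitespace
#'   trimming.
#' @return A symmetric p x p numeric matrix with feature names as dimnames.
#' @export
build_feature_distance_matrix <- function(edges, feature_to_gene) {
  map <- tibble::as_tibble(feature_to_gene[, 1:2])
  names(map) <- c("feature", "gene")
  map$feature <- trimws(as.character(map$feature))
  map$gene <- trimws(as.character(map$gene))
  features <- unique(map$feature)
  p <- length(features)

  genes_known <- unique(c(edges$id_a, edges$id_b, map$gene))
  unmapped <- setdiff(features, map$feature[map$gene %in% genes_known])
  # features sharing a gene
  shared <- dplyr::inner_join(map, map, by = "gene",
                              relationship = "many-to-many")
  shared <- shared[shared$feature.x < shared$feature.y, ]
  pairs1 <- unique(shared[c("feature.x", "feature.y")])
  # features whose genes interact
  fa <- dplyr::inner_join(edges, map, by = c(id_a = "gene"),
                          relationship = "many-to-many")
  fab <- dplyr::inner_join(fa, map, by = c(id_b = "gene"),
                           relationship = "many-to-many",
                           suffix = c(".x", ".y"))
  fab <- fab[fab$feature.x != fab$feature.y, ]
  pairs2 <- unique(tibble::tibble(
    feature.x = pmin(fab$feature.x, fab$feature.y),
    feature.y = pmax(fab$feature.x, fab$feature.y)))
  pairs <- unique(dplyr::bind_rows(pairs1, pairs2))

  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = features)
  if (nrow(pairs) > 0L) {
    g <- igraph::add_edges(g, rbind(match(pairs$feature.x, features),
                                    match(pairs$feature.y, features)))
  }
  D <- igraph::distances(g)
  D <- D[features, features]
  iso <- features[igraph::degree(g) == 0]
  if (length(iso) > 0L) {
    message(length(iso), " feature(s) with no interactions: self-only ",
            "neighbourhoods (", paste(utils::head(iso, 5), collapse = ", "),
            if (length(iso) > 5) ", ..." else "", ")")
  }
  D
}

#' Threshold a distance matrix into LAVA neighbourhoods
#'
#' For each feature j, the neighbourhood is the sorted set of features within
#' hop distance `theta`, always including j itself. `theta = 0` yields
#' identity neighbourhoods, under which LAVA models reproduce their plain
#' counterparts exactly.
#'
#' @param dist_matrix Symmetric distance matrix (e.g. from
#'   [build_feature_distance_matrix()], or a `$distances` component of
#'   [synthetic_planted()]).
#' @param theta Non-negative distance threshold.
#' @return A named list of sorted integer index vectors, one per feature,
#'   with attribute `theta`; pass it as `neighbourhoods` to the model
#'   fitters.
#' @export
neighbourhoods <- function(dist_matrix, theta) {
  stopifnot(theta >= 0, nrow(dist_matrix) == ncol(dist_matrix))
  p <- nrow(dist_matrix)
  out <- lapply(seq_len(p), function(j) {
    sort(unique(c(j, which(dist_matrix[j, ] <= theta))))
  })
  names(out) <- rownames(dist_matrix)
  attr(out, "theta") <- theta
  out
}

#' Identity neighbourhoods (every feature alone)
#'
#' @param p Number of features.
#' @return A list of singleton index vectors.
#' @export
identity_neighbourhoods <- function(p) {
  lapply(seq_len(p), identity)
}

#' Write a distance matrix as delimited text
#'
#' @param dist_matrix Matrix from [build_feature_distance_matrix()].
#' @param path Output file; comma-separated with header row and a leading
#'   `feature` column. Infinite entries are written as `Inf`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist_matrix, path) {
  df <- tibble::as_tibble(as.data.frame(dist_matrix), rownames = "feature")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input file.
#' @return A numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  m
}
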