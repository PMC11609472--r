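#' @importFrom rlang := .data
#' @importFrom stats predict
NULL

# Internal canonical form: numeric matrix X, factor y (NULL for regression),
# feature names and sample ids. All user-facing functions accept a data frame
# with one label column and convert through here.
new_dataset <- function(X, y = NULL, feature_names = colnames(X),
                        sample_ids = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(X)))
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (!is.null(y)) {
    y <- factor(y)
    if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
    if (length(y) != nrow(X)) stop("label length != sample count", call. = FALSE)
  }
  colnames(X) <- feature_names
  list(X = X, y = y, feature_names = feature_names, sample_ids = sample_ids)
}

# Split a data frame into features + label by column name (string or bare name).
as_dataset <- function(data, label) {
  label <- rlang::as_name(rlang::ensym(label))
  if (!label %in% names(data)) {
    stop("label column '", label, "' not found in data", call. = FALSE)
  }
  y <- data[[label]]
  feats <- data[setdiff(names(data), label)]
  not_num <- !vapply(feats, is.numeric, logical(1))
  if (any(not_num)) {
    stop("non-numeric feature columns: ",
         paste(names(feats)[not_num], collapse = ", "), call. = FALSE)
  }
  new_dataset(as.matrix(feats), y)
}

# Validate a neighbourhood index against p features; returns a list of sorted
# integer vectors, each containing its own index.
check_neighbourhoods <- function(neighbourhoods, p) {
  if (is.null(neighbourhoods)) return(NULL)
  if (length(neighbourhoods) != p) {
    stop("neighbourhood index must cover all ", p, " features", call. = FALSE)
  }
  lapply(seq_len(p), function(j) {
    nb <- as.integer(neighbourhoods[[j]])
    if (any(nb < 1L | nb > p)) stop("neighbourhood indices out of range", call. = FALSE)
    sort(unique(c(j, nb)))
  })
}

# max_features spec -> integer count
resolve_max_features <- function(max_features, p) {
  if (is.character(max_features)) {
    m <- switch(max_features,
                sqrt = max(1L, floor(sqrt(p))),
                all = p,
                stop("max_features must be 'sqrt', 'all' or an integer",
                     call. = FALSE))
    return(as.integer(m))
  }
  m <- as.integer(max_features)
  if (is.na(m) || m < 1L || m > p) {
    stop("integer max_features must lie in [1, p]", call. = FALSE)
  }
  m
}

# Seeds derived from one master seed; kept below 2^31 for R's integer RNG API.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
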