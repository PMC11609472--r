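#' Fisher Iris with three appended noise features
#'
#' The four classic Iris measurements plus one Gaussian, one uniform and one
#' bimodal noise column, used to benchmark directional importance against
#' features with no class information. Noise distributions are anchored to
#' the pooled original measurements: Gaussian with the pooled mean and
#' standard deviation; uniform over the pooled min-max range; bimodal as an
#' equal mixture of two Gaussians centred 1.5 pooled standard deviations
#' either side of the pooled mean, each with half the pooled standard
#' deviation.
#'
#' @param seed Integer seed; output is fully deterministic given it.
#' @return Tibble of 150 rows: `sepal_length`, `sepal_width`, `petal_length`,
#'   `petal_width`, `noise_gaussian`, `noise_uniform`, `noise_bimodal` and
#'   the factor label `species` (50 per class).
#' @examples
#' d <- iris_with_noise(seed = 1)
#' dplyr::count(d, species)
#' @export
iris_with_noise <- function(seed = 1L) {
  ir <- datasets::iris
  X <- as.matrix(ir[, 1:4])
  pooled <- as.vector(X)
  mu <- mean(pooled)
  sdp <- stats::sd(pooled)
  n <- nrow(X)
  withr::with_seed(as.integer(seed), {
    gaussian <- stats::rnorm(n, mu, sdp)
    unif <- stats::runif(n, min(pooled), max(pooled))
    side <- sample(c(-1, 1), n, replace = TRUE)
    bimodal <- stats::rnorm(n, mu + side * 1.5 * sdp, 0.5 * sdp)
  })
  tibble::tibble(
    sepal_length = X[, 1L], sepal_width = X[, 2L],
    petal_length = X[, 3L], petal_width = X[, 4L],
    noise_gaussian = gaussian, noise_uniform = unif,
    noise_bimodal = bimodal,
    species = factor(ir$Species))
}

#' Permute each feature column independently
#'
#' Shuffles the values within every feature column (labels untouched),
#' preserving each column's marginal distribution while breaking all
#' feature-label and feature-feature associations. This is the standard
#' negative control: a model fitted to the permuted data should collapse to
#' chance and its importance distributions should centre at zero.
#'
#' @param data Data frame with numeric features and one label column.
#' @param label Label column (bare name or string), left untouched.
#' @param seed Integer seed.
#' @return A tibble of the same shape.
#' @export
permute_within_columns <- function(data, label, seed = 1L) {
  label <- rlang::as_name(rlang::ensym(label))
  if (!label %in% names(data)) {
    stop("label column '", label, "' not found", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  feats <- setdiff(names(out), label)
  withr::with_seed(as.integer(seed), {
    for (f in feats) out[[f]] <- sample(out[[f]])
  })
  out
}

#' Planted-signal multi-class synthetic data
#'
#' Generates a baseline Gaussian feature matrix with known, class-specific
#' directional effects and optional correlated feature blocks tied to a known
#' graph -- a stand-in for multi-class omics matrices (e.g. tumour proteomics)
#' where the ground truth is unknowable. Informative (feature, class) pairs
#' shift that class's samples by `effect` noise standard deviations;
#' correlated blocks share a latent factor so that block members are
#' exchangeable neighbours for latent-variable splits. The emitted truth
#' table and block-distance matrix support direction-recovery checks.
#'
#' @param n_classes Number of classes.
#' @param n_per_class Samples per class.
#' @param n_features Number of features.
#' @param informative Tibble/data frame with columns `feature` (index),
#'   `class` (index) and `effect` (signed shift in noise-sd units), or `NULL`
#'   for the default plant: two features per class with effects
#'   `+effect_size` and `-effect_size`.
#' @param blocks List of integer feature groups generated with a shared
#'   latent factor, or `NULL` for the default: each informative feature is
#'   paired with one otherwise-null partner feature. Block membership defines
#'   distance 1 in the emitted distance matrix.
#' @param rho Within-block correlation, `|rho| < 1`.
#' @param effect_size Default effect magnitude (noise-sd units) used when
#'   `informative` is `NULL`.
#' @param noise_sd Baseline feature standard deviation.
#' @param seed Integer seed.
#' @return List with `data` (tibble, label column `class`), `truth` (tibble
#'   `feature`, `class`, `effect`, `sign`) and `distances` (p x p matrix:
#'   0 diagonal, 1 within blocks, `Inf` elsewhere).
#' @examples
#' sim <- synthetic_planted(n_classes = 3, n_per_class = 20,
#'                          n_features = 10, seed = 1)
#' sim$truth
#' @export
synthetic_planted <- function(n_classes = 4L, n_per_class = 30L,
                              n_features = 20L, informative = NULL,
                              blocks = NULL, rho = 0.7, effect_size = 1.5,
                              noise_sd = 1, seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (is.null(informative)) {
    need <- 2L * n_classes
    if (need > n_features) {
      stop("default plant needs at least 2 features per class", call. = FALSE)
    }
    informative <- tibble::tibble(
      feature = seq_len(need),
      class = rep(seq_len(n_classes), each = 2L),
      effect = rep(c(effect_size, -effect_size), times = n_classes))
  }
  informative <- tibble::as_tibble(informative)
  if (any(informative$feature < 1L | informative$feature > n_features) ||
      any(informative$class < 1L | informative$class > n_classes)) {
    stop("informative entries reference invalid features or classes",
         call. = FALSE)
  }
  if (is.null(blocks)) {
    inf_feats <- unique(informative$feature)
    partners <- setdiff(seq_len(n_features), inf_feats)
    blocks <- list()
    for (i in seq_along(inf_feats)) {
      if (i > length(partners)) break
      blocks[[i]] <- c(inf_feats[i], partners[i])
    }
  }
  for (b in blocks) {
    if (any(b < 1L | b > n_features)) {
      stop("block indices out of range", call. = FALSE)
    }
  }

  n <- n_classes * n_per_class
  classes <- factor(rep(paste0("C", seq_len(n_classes)),
                        each = n_per_class))
  withr::with_seed(as.integer(seed), {
    X <- matrix(stats::rnorm(n * n_features, 0, noise_sd), n, n_features)
    for (b in blocks) {
      z <- stats::rnorm(n)
      for (f in b) {
        X[, f] <- noise_sd * (sqrt(rho) * z +
                                sqrt(1 - rho) * stats::rnorm(n))
      }
    }
  })
  for (i in seq_len(nrow(informative))) {
    rows <- as.integer(classes) == informative$class[i]
    X[rows, informative$feature[i]] <- X[rows, informative$feature[i]] +
      informative$effect[i] * noise_sd
  }

  feature_names <- sprintf("f%02d", seq_len(n_features))
  colnames(X) <- feature_names
  D <- matrix(Inf, n_features, n_features,
              dimnames = list(feature_names, feature_names))
  for (b in blocks) D[b, b] <- 1
  diag(D) <- 0

  truth <- tibble::tibble(
    feature = feature_names[informative$feature],
    class = paste0("C", informative$class),
    effect = informative$effect,
    sign = sign(informative$effect))

  data <- tibble::as_tibble(as.data.frame(X))
  data$class <- classes
  list(data = data, truth = truth, distances = D)
}
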