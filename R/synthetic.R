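# Deterministic generator of mental-health-assessment-like datasets:
# Likert-style questionnaire items plus continuous activity features
# (post counts, session durations) with a latent risk-class label.

#' Synthetic-data generator configuration
#'
#' @param n_samples Number of records.
#' @param n_classes Number of latent classes (default 3, e.g. low /
#'   moderate / high risk).
#' @param n_likert_items Number of categorical attributes with 5 ordered
#'   response levels ("1".."5").
#' @param n_continuous Number of continuous activity features.
#' @param class_weights Class prior probabilities (default uniform);
#'   must sum to 1.
#' @param separation Distance between class-conditional means of the
#'   continuous features, in within-class standard deviations (>= 0).
#'   Also controls how concentrated the Likert responses are around each
#'   class's modal level; 0 means no signal in either block.
#' @param label_noise Probability in [0, 0.5) of replacing a record's
#'   label with a different, uniformly chosen class.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples, n_classes = 3L, n_likert_items = 6L,
                             n_continuous = 4L, class_weights = NULL,
                             separation = 2.5, label_noise = 0.05,
                             seed = 42L) {
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (n_likert_items < 0L || n_continuous < 0L ||
      n_likert_items + n_continuous < 1L) {
    stop("need at least one attribute", call. = FALSE)
  }
  if (is.null(class_weights)) class_weights <- rep(1 / n_classes, n_classes)
  if (length(class_weights) != n_classes ||
      abs(sum(class_weights) - 1) > 1e-9 || any(class_weights < 0)) {
    stop("`class_weights` must be ", n_classes,
         " non-negative values summing to 1", call. = FALSE)
  }
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("`label_noise` must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(n_samples = n_samples, n_classes = n_classes,
                 n_likert_items = as.integer(n_likert_items),
                 n_continuous = as.integer(n_continuous),
                 class_weights = as.numeric(class_weights),
                 separation = separation, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "generator_config")
}

LIKERT_LEVELS <- as.character(1:5)

# Class-conditional mean directions for the continuous block: unit
# vectors at pairwise distance sqrt(2), scaled so class means sit
# `separation` within-class standard deviations apart.
class_mean_matrix <- function(n_classes, n_continuous, separation) {
  if (n_continuous == 0L) return(matrix(0, n_classes, 0L))
  U <- matrix(0, n_classes, n_continuous)
  for (c in seq_len(n_classes)) U[c, ((c - 1L) %% n_continuous) + 1L] <- 1
  separation / sqrt(2) * U
}

# Likert response distribution for one class: probabilities decay
# geometrically with distance from the class's modal level; at
# separation 0 the distribution is uniform.
likert_probs <- function(class_idx, n_classes, separation) {
  mode_lv <- 1 + round((class_idx - 1) * 4 / max(1, n_classes - 1))
  w <- exp(-0.5 * separation * abs(seq_len(5) - mode_lv))
  w / sum(w)
}

#' Generate a synthetic assessment dataset
#'
#' Draws a latent class for each record from `class_weights`, then
#' continuous activity features from class-conditional Gaussians (means
#' `separation` standard deviations apart, unit variance) and Likert
#' items from class-conditional multinomials whose modal level shifts
#' with the class index. Finally each label is replaced, with
#' probability `label_noise`, by a different class drawn uniformly.
#'
#' @param config A [generator_config()].
#' @return An [mh_dataset()] with classes `"C1"`, `"C2"`, ... Likert
#'   columns `likert_1..` (levels "1".."5") and continuous columns
#'   `activity_1..`.
#' @export
#' @examples
#' d <- generate_dataset(generator_config(100, seed = 1))
#' table(dataset_labels(d))
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  K <- config$n_classes
  classes <- paste0("C", seq_len(K))
  attrs <- c(
    lapply(seq_len(config$n_likert_items), function(i) {
      attribute_spec(paste0("likert_", i), "categorical",
                     levels = LIKERT_LEVELS)
    }),
    lapply(seq_len(config$n_continuous), function(i) {
      attribute_spec(paste0("activity_", i), "continuous")
    })
  )
  schema <- mh_schema(attrs, "mh_class", classes)
  n <- config$n_samples
  mu <- class_mean_matrix(K, config$n_continuous, config$separation)
  lik_p <- lapply(seq_len(K), function(c) {
    likert_probs(c, K, config$separation)
  })
  df <- with_seed(config$seed, {
    z <- sample.int(K, n, replace = TRUE, prob = config$class_weights)
    cols <- list()
    for (j in seq_len(config$n_likert_items)) {
      v <- character(n)
      for (c in seq_len(K)) {
        idx <- which(z == c)
        v[idx] <- sample(LIKERT_LEVELS, length(idx), replace = TRUE,
                         prob = lik_p[[c]])
      }
      cols[[paste0("likert_", j)]] <- v
    }
    for (j in seq_len(config$n_continuous)) {
      cols[[paste0("activity_", j)]] <- stats::rnorm(n, mean = mu[z, j])
    }
    lab <- z
    if (config$label_noise > 0) {
      flip <- stats::runif(n) < config$label_noise
      for (i in which(flip)) {
        lab[i] <- sample(setdiff(seq_len(K), z[i]), 1L)
      }
    }
    cols$mh_class <- classes[lab]
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
  mh_dataset(df, schema)
}

#' Default synthetic benchmark
#'
#' The study conditions used throughout the package's experiments:
#' 2000 records, 3 classes, 6 Likert items, 4 continuous activity
#' features, separation 2.5, label noise 0.05 — divided into 10 equal
#' parts of which six form the training set and four the test set.
#'
#' @param seed Integer seed driving both generation and the split.
#' @return List with `train` (1200 records) and `test` (800 records).
#' @export
default_benchmark <- function(seed = 42L) {
  d <- generate_dataset(generator_config(2000L, seed = seed))
  split_train_test(d, n_parts = 10L, n_train = 6L, seed = seed)
}
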