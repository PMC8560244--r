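# Small fixtures shared across test files; everything is built in code.

# One continuous attribute, labels A,A,B,B on x = 1..4 — separable at 2.5.
fixture_xsep <- function() {
  sch <- mh_schema(list(attribute_spec("x", "continuous")), "cls", c("A", "B"))
  mh_dataset(data.frame(x = c(1, 2, 3, 4), cls = c("A", "A", "B", "B")), sch)
}

# Mixed-type schema with a categorical and a continuous attribute.
fixture_mixed <- function(n = 40, seed = 7) {
  sch <- mh_schema(
    list(attribute_spec("mood", "categorical", levels = c("low", "mid", "high")),
         attribute_spec("posts", "continuous")),
    "cls", c("A", "B"))
  df <- with_seed_test(seed, {
    cls <- rep(c("A", "B"), length.out = n)
    data.frame(
      mood = ifelse(cls == "A",
                    sample(c("low", "mid"), n, replace = TRUE),
                    sample(c("mid", "high"), n, replace = TRUE)),
      posts = ifelse(cls == "A", rnorm(n, 0), rnorm(n, 3)),
      cls = cls, stringsAsFactors = FALSE)
  })
  mh_dataset(df, sch)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# XOR task: 4 samples, 2 inputs, one-hot 2-class targets.
fixture_xor <- function() {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(1, 2, 2, 1)
  Y <- matrix(0, 4, 2); Y[cbind(1:4, y)] <- 1
  list(X = X, Y = Y)
}

# A probe classifier that always predicts the first class with
# certainty, used to check the accounting in classification_report.
constant_majority_clf <- function(classes) {
  structure(list(classes = classes), class = "constant_clf")
}
registerS3method("predict", "constant_clf",
                 function(object, newdata, type = "prob", ...) {
                   n <- n_records(newdata)
                   matrix(rep(c(1, 0), each = n), n, 2,
                          dimnames = list(NULL, object$classes))
                 },
                 envir = asNamespace("stats"))

# Brute-force gain ratio straight from the defining formulas, kept
# independent of the package's exact_gain_ratio implementation.
bf_entropy <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}
bf_gain_ratio <- function(parent, branches) {
  s <- sum(parent)
  bt <- rowSums(branches)
  info_a <- sum(bt / s * apply(branches, 1, bf_entropy))
  gain <- bf_entropy(parent) - info_a
  si <- bf_entropy(bt)
  list(gain = gain, split_info = si, gain_ratio = gain / si)
}
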