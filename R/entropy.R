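# Exact and polynomial-approximated information measures.
#
# The TAM ("Taylor/Maclaurin") path replaces every logarithm in the
# gain-ratio formula with a third-order Maclaurin polynomial of ln(x)
# about x = 1, so that candidate scoring uses only elementary arithmetic.
# An instrumented counter tracks transcendental-log calls so that the
# zero-log property of the TAM path can be asserted.

# 1/ln(2), fixed so the approximated path performs no log() call at all.
INV_LN2 <- 1.4426950408889634

ZERO_TOL <- 1e-12

.log_counter <- new.env(parent = emptyenv())
.log_counter$n <- 0

count_logs <- function(k) {
  .log_counter$n <- .log_counter$n + k
  invisible(NULL)
}

#' Transcendental-log call counter
#'
#' The exact entropy/gain-ratio path increments an internal counter every
#' time it evaluates a logarithm; the Maclaurin-approximated path never
#' does. Reading and resetting the counter lets callers verify that
#' TAM-mode scoring is log-free.
#'
#' @return `log_call_count()` returns the number of logarithm evaluations
#'   recorded since the last reset; `reset_log_counter()` zeroes the
#'   counter and returns the previous value invisibly.
#' @export
log_call_count <- function() .log_counter$n

#' @rdname log_call_count
#' @export
reset_log_counter <- function() {
  old <- .log_counter$n
  .log_counter$n <- 0
  invisible(old)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(counts < 0) || any(!is.finite(counts))) {
    stop("class counts must be finite and non-negative", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("class counts must total at least 1", call. = FALSE)
  }
  counts
}

#' Exact class-entropy in bits
#'
#' Shannon entropy \eqn{-\sum_i p_i \log_2 p_i} of a class-count vector,
#' with the convention \eqn{0 \log 0 = 0}. The result lies in
#' \eqn{[0, \log_2 m]} for \eqn{m} classes.
#'
#' @param counts Non-negative per-class counts with positive total.
#' @return Entropy in bits.
#' @export
#' @examples
#' exact_entropy(c(7, 7))  # 1 bit
#' exact_entropy(c(4, 0))  # 0 bits
exact_entropy <- function(counts) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  count_logs(length(p))
  -sum(p * log2(p))
}

#' Third-order Maclaurin approximation of the natural logarithm
#'
#' Evaluates the polynomial
#' \eqn{(x-1) - (x-1)^2/2 + (x-1)^3/3}, the Maclaurin expansion of
#' \eqn{\ln x} about \eqn{x = 1} truncated after the cubic term. Only
#' defined on \eqn{(0, 1]}, the range probabilities take in the
#' gain-ratio formula.
#'
#' @param x Numeric vector with all elements in (0, 1].
#' @return Polynomial approximation of \eqn{\ln x} (vectorized).
#' @export
#' @examples
#' maclaurin_ln(1)    # 0
#' maclaurin_ln(0.5)  # -0.6667 (true value -0.6931)
maclaurin_ln <- function(x) {
  if (any(x <= 0) || any(x > 1)) {
    stop("maclaurin_ln is defined on (0, 1] only", call. = FALSE)
  }
  u <- x - 1
  u - u^2 / 2 + u^3 / 3
}

#' Polynomial form of p*ln(p) for a count ratio
#'
#' Closed polynomial form of \eqn{(a/b)\,\mathrm{maclaurin\_ln}(a/b)}:
#' \deqn{\frac{a(a-b)(2a^2 - 7ab + 11b^2)}{6b^4},}
#' evaluated with arithmetic only (no logarithm). Returns 0 when
#' \eqn{a = 0} or \eqn{a = b}.
#'
#' @param a Numerator count(s), \eqn{0 \le a \le b} (vectorized).
#' @param b Denominator count, \eqn{b \ge 1}.
#' @return Approximation of \eqn{(a/b)\ln(a/b)} in nats (non-positive).
#' @export
#' @examples
#' approx_plogp(1, 2)  # -1/3
approx_plogp <- function(a, b) {
  if (any(b < 1)) stop("`b` must be at least 1", call. = FALSE)
  if (any(a < 0) || any(a > b)) {
    stop("require 0 <= a <= b", call. = FALSE)
  }
  a * (a - b) * (2 * a^2 - 7 * a * b + 11 * b^2) / (6 * b^4)
}

#' Maclaurin-approximated class-entropy in bits
#'
#' The category-entropy analogue of [exact_entropy()] with every
#' \eqn{p \ln p} term replaced by its polynomial surrogate:
#' \eqn{-(1/\ln 2) \sum_i \mathrm{approx\_plogp}(s_i, s)}.
#'
#' @inheritParams exact_entropy
#' @return Approximated entropy in bits.
#' @export
#' @examples
#' approx_entropy(c(7, 7))  # 0.961797 (exact value 1)
approx_entropy <- function(counts) {
  counts <- check_counts(counts)
  -INV_LN2 * sum(approx_plogp(counts, sum(counts)))
}

check_partition <- function(parent, branches) {
  branches <- as.matrix(branches)
  if (ncol(branches) != length(parent)) {
    stop("branch table must have one column per class", call. = FALSE)
  }
  if (any(branches < 0)) stop("branch counts must be non-negative", call. = FALSE)
  tot <- colSums(branches)
  if (any(abs(tot - parent) > ZERO_TOL)) {
    stop("branch counts must sum to the parent counts", call. = FALSE)
  }
  branches
}

invalid_candidate <- function() {
  list(gain = NA_real_, split_info = NA_real_, gain_ratio = NA_real_,
       valid = FALSE)
}

#' Exact information gain ratio of a candidate partition
#'
#' Scores the split of a parent class-count vector into branches: the
#' information gain is the entropy reduction
#' \eqn{\mathrm{Info}(S) - \sum_j (s_j/s)\,\mathrm{Info}(S_j)}, the split
#' information is the entropy of the branch sizes, and the gain ratio is
#' their quotient — the C4.5 splitting criterion.
#'
#' @param parent Per-class counts at the node.
#' @param branches Matrix of counts, one row per branch and one column
#'   per class; column sums must equal `parent`.
#' @return A split candidate: list with `gain`, `split_info`,
#'   `gain_ratio` (all in bits / dimensionless) and `valid`. A partition
#'   that puts every record in one branch has zero split information and
#'   is flagged invalid rather than raising an error.
#' @export
#' @examples
#' exact_gain_ratio(c(9, 5), rbind(c(6, 2), c(3, 3)))
exact_gain_ratio <- function(parent, branches) {
  parent <- check_counts(parent)
  branches <- check_partition(parent, branches)
  s <- sum(parent)
  bt <- rowSums(branches)
  if (sum(bt > 0) < 2L) return(invalid_candidate())
  info_a <- sum(vapply(which(bt > 0), function(j) {
    bt[j] / s * exact_entropy(branches[j, ])
  }, numeric(1)))
  gain <- exact_entropy(parent) - info_a
  split_info <- exact_entropy(bt)
  if (split_info <= ZERO_TOL) return(invalid_candidate())
  list(gain = gain, split_info = split_info,
       gain_ratio = gain / split_info, valid = TRUE)
}

#' Maclaurin-approximated information gain ratio (TAM scoring)
#'
#' The gain-ratio formula with every entropy term computed through
#' [approx_plogp()] instead of a logarithm:
#' \deqn{\mathrm{GainRatio}'(A) =
#'   \frac{\mathrm{Info}'(S) - \mathrm{Info}_A'(S)}{\mathrm{Info}'(A)},}
#' where \eqn{\mathrm{Info}_A'(S) = -(1/\ln 2)\sum_j (s_j/s)\sum_i
#' \mathrm{approx\_plogp}(s_{ij}, s_j)} and \eqn{\mathrm{Info}'(A) =
#' -(1/\ln 2)\sum_j \mathrm{approx\_plogp}(s_j, s)}. The per-candidate
#' path performs no transcendental-log call; multiplying all three terms
#' by a common positive constant leaves the ratio unchanged, which is why
#' dropping or retaining the \eqn{1/\ln 2} prefactor cannot reorder
#' candidates.
#'
#' @inheritParams exact_gain_ratio
#' @return A split candidate as in [exact_gain_ratio()], with
#'   `gain` the approximated entropy reduction. Flagged invalid when the
#'   approximated split information is zero.
#' @export
approx_gain_ratio <- function(parent, branches) {
  parent <- check_counts(parent)
  branches <- check_partition(parent, branches)
  s <- sum(parent)
  bt <- rowSums(branches)
  if (sum(bt > 0) < 2L) return(invalid_candidate())
  nz <- which(bt > 0)
  info_a <- -INV_LN2 * sum(vapply(nz, function(j) {
    bt[j] / s * sum(approx_plogp(branches[j, ], bt[j]))
  }, numeric(1)))
  info_s <- -INV_LN2 * sum(approx_plogp(parent, s))
  split_info <- -INV_LN2 * sum(approx_plogp(bt, s))
  if (split_info <= ZERO_TOL) return(invalid_candidate())
  gain <- info_s - info_a
  list(gain = gain, split_info = split_info,
       gain_ratio = gain / split_info, valid = TRUE)
}

#' Best equal-division-point split of a continuous attribute
#'
#' Supervised discretization: with `MIN` and `MAX` the extremes of the
#' observed values, the candidate thresholds are the interior
#' equal-division points
#' \eqn{A_i = \mathrm{MIN} + i\,(\mathrm{MAX}-\mathrm{MIN})/(N+1)},
#' \eqn{i = 1, \dots, N}. Each threshold induces the binary partition
#' (values \eqn{\le A_i}) / (values \eqn{> A_i}); the candidate with the
#' largest gain ratio wins, ties going to the smaller threshold.
#'
#' @param values Numeric attribute values (length >= 2).
#' @param labels Class labels, same length as `values`.
#' @param n_points Number of equal-division candidate thresholds
#'   (default 10).
#' @param mode `"exact"` for logarithmic scoring, `"tam"` for the
#'   Maclaurin-approximated scoring that avoids log calls.
#' @param class_levels Optional ordered class labels; defaults to the
#'   levels of `labels`.
#' @param midpoints If `TRUE`, use the classic C4.5 candidate set
#'   (midpoints between consecutive distinct sorted values) instead of
#'   equal-division points. Off by default.
#' @return A split candidate as in [exact_gain_ratio()], with an extra
#'   `threshold` element. When all values are identical (or no candidate
#'   induces two non-empty branches) the candidate is invalid.
#' @export
#' @examples
#' discretize_continuous(c(1, 2, 3, 4), c("A", "A", "B", "B"), n_points = 3)
discretize_continuous <- function(values, labels, n_points = 10L,
                                  mode = c("exact", "tam"),
                                  class_levels = NULL, midpoints = FALSE) {
  mode <- match.arg(mode)
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("`n_points` must be at least 1", call. = FALSE)
  if (length(values) != length(labels) || length(values) < 2L) {
    stop("`values` and `labels` must have equal length >= 2", call. = FALSE)
  }
  if (is.null(class_levels)) {
    class_levels <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  }
  labels <- factor(labels, levels = class_levels)
  lo <- min(values); hi <- max(values)
  if (hi - lo <= ZERO_TOL) {
    out <- invalid_candidate(); out$threshold <- NA_real_; return(out)
  }
  thresholds <- if (midpoints) {
    sv <- sort(unique(values))
    (sv[-length(sv)] + sv[-1]) / 2
  } else {
    lo + seq_len(n_points) * (hi - lo) / (n_points + 1)
  }
  score <- if (mode == "tam") approx_gain_ratio else exact_gain_ratio
  parent <- as.numeric(table(labels))
  best <- invalid_candidate(); best$threshold <- NA_real_
  for (thr in thresholds) {
    left <- values <= thr
    if (!any(left) || all(left)) next
    branches <- rbind(as.numeric(table(labels[left])),
                      as.numeric(table(labels[!left])))
    cand <- score(parent, branches)
    if (!cand$valid) next
    if (!isTRUE(best$valid) || cand$gain_ratio > best$gain_ratio + ZERO_TOL) {
      best <- cand
      best$threshold <- thr
    }
  }
  best
}
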