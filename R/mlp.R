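# Multilayer perceptron with sigmoid hidden units.
#
# Two training objectives are supported:
#  * softmax head + classification cross-entropy, minimized by full-batch
#    gradient descent;
#  * sigmoid output units + sum-squared error E = 1/2 * sum (d - y)^2,
#    minimized by the Levenberg-Marquardt damped Gauss-Newton rule
#    delta = -(J'J + mu I)^{-1} J' e  with residuals e = d - y.

#' Training configuration for the perceptron
#'
#' @param objective `"cross_entropy_gd"` (softmax head, gradient descent)
#'   or `"sse_lm"` (sigmoid outputs, Levenberg-Marquardt).
#' @param learning_rate Gradient-descent step size (> 0).
#' @param lambda L2 penalty strength applied as `lambda/(2m) * sum(theta^2)`
#'   over weights (biases excluded).
#' @param mu0 Initial Levenberg-Marquardt damping (> 0).
#' @param mu_factor Multiplicative damping schedule (> 1): divide on an
#'   accepted step, multiply on a rejected one.
#' @param max_iters Iteration cap.
#' @param tol Stop when the loss improvement falls below this value.
#' @param seed Seed recorded with the run (initialization happens in
#'   [mlp_init()]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(objective = c("sse_lm", "cross_entropy_gd"),
                         learning_rate = 0.5, lambda = 0,
                         mu0 = 1e-3, mu_factor = 10,
                         max_iters = 200L, tol = 1e-9, seed = 42L) {
  objective <- match.arg(objective)
  if (learning_rate < 0) stop("`learning_rate` must be >= 0", call. = FALSE)
  if (mu0 <= 0) stop("`mu0` must be > 0", call. = FALSE)
  if (mu_factor <= 1) stop("`mu_factor` must be > 1", call. = FALSE)
  structure(list(objective = objective, learning_rate = learning_rate,
                 lambda = lambda, mu0 = mu0, mu_factor = mu_factor,
                 max_iters = as.integer(max_iters), tol = tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize perceptron parameters
#'
#' Weights are drawn uniformly on \eqn{[-r, r]} with
#' \eqn{r = \sqrt{6/(\mathrm{fan~in} + \mathrm{fan~out})}} per layer;
#' biases start at zero. Fully deterministic given `seed`.
#'
#' @param layer_sizes Integer vector of at least three layer widths
#'   (input, hidden(s), output), all >= 1.
#' @param seed Integer seed.
#' @return An object of class `mlp`: list with `layer_sizes`, `weights`
#'   (list of fan-in x fan-out matrices) and `biases` (list of vectors).
#' @export
mlp_init <- function(layer_sizes, seed = 42L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L || any(layer_sizes < 1L)) {
    stop("`layer_sizes` needs >= 3 layers, all sizes >= 1", call. = FALSE)
  }
  L <- length(layer_sizes) - 1L
  params <- with_seed(seed, {
    w <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fi <- layer_sizes[l]; fo <- layer_sizes[l + 1L]
      r <- sqrt(6 / (fi + fo))
      w[[l]] <- matrix(stats::runif(fi * fo, -r, r), fi, fo)
      b[[l]] <- rep(0, fo)
    }
    list(weights = w, biases = b)
  })
  structure(list(layer_sizes = layer_sizes, weights = params$weights,
                 biases = params$biases),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("<mlp> layers ", paste(x$layer_sizes, collapse = "-"),
      ", ", n_params(x), " parameters\n", sep = "")
  invisible(x)
}

#' Total parameter count of a perceptron
#' @param params An [mlp_init()] object.
#' @return Integer number of weights plus biases.
#' @export
n_params <- function(params) {
  sum(vapply(params$weights, length, integer(1))) +
    sum(vapply(params$biases, length, integer(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Numerically stable softmax
#'
#' \eqn{e^{a_k} / \sum_q e^{a_q}} computed row-wise with max-subtraction
#' so large logits cannot overflow.
#'
#' @param logits Numeric vector, or matrix with one row per sample.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
#' @examples
#' softmax(c(1, 0))
softmax <- function(logits) {
  if (is.null(dim(logits))) {
    if (length(logits) == 0L) stop("empty logit vector", call. = FALSE)
    z <- exp(logits - max(logits))
    return(z / sum(z))
  }
  if (ncol(logits) == 0L) stop("empty logit matrix", call. = FALSE)
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

#' Forward pass through the perceptron
#'
#' Hidden layers apply the sigmoid squashing function
#' \eqn{1/(1+e^{-z})}; the final layer's pre-activation is returned
#' together with both heads: the softmax probabilities (classification /
#' cross-entropy) and the sigmoid outputs (sum-squared-error objective).
#'
#' @param params An [mlp_init()] object.
#' @param X Numeric matrix, one sample per row; column count must equal
#'   the input layer size.
#' @return List with `hidden` (list of hidden activation matrices),
#'   `logits` (final pre-activation), `probs` (softmax head) and
#'   `sigout` (sigmoid head).
#' @export
mlp_forward <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != params$layer_sizes[1L]) {
    stop("input width ", ncol(X), " does not match input layer size ",
         params$layer_sizes[1L], call. = FALSE)
  }
  L <- length(params$weights)
  hidden <- vector("list", L - 1L)
  a <- X
  for (l in seq_len(L - 1L)) {
    a <- sigmoid(sweep(a %*% params$weights[[l]], 2L, params$biases[[l]], "+"))
    hidden[[l]] <- a
  }
  logits <- sweep(a %*% params$weights[[L]], 2L, params$biases[[L]], "+")
  list(hidden = hidden, logits = logits,
       probs = softmax(logits), sigout = sigmoid(logits))
}

check_onehot <- function(Y, width) {
  Y <- as.matrix(Y)
  if (ncol(Y) != width) {
    stop("target width does not match output layer size", call. = FALSE)
  }
  ok <- apply(Y, 1L, function(r) all(r %in% c(0, 1)) && sum(r) == 1)
  if (!all(ok)) stop("targets must be one-hot rows", call. = FALSE)
  Y
}

# The squared-error objective also accepts binary (0/1) targets for a
# single output unit, where a one-hot row constraint is meaningless.
check_targets01 <- function(Y, width) {
  Y <- as.matrix(Y)
  if (ncol(Y) == 1L) {
    if (!all(Y %in% c(0, 1))) {
      stop("targets must be 0/1", call. = FALSE)
    }
    return(Y)
  }
  check_onehot(Y, width)
}

EPS_CLIP <- 1e-12

#' Classification cross-entropy loss
#'
#' \eqn{-\sum_i \sum_k y_{ik} \ln \hat y_{ik} + \frac{\lambda}{2m}
#' \sum \theta^2} with \eqn{\hat y} the softmax head, predictions clipped
#' to \eqn{[10^{-12}, 1-10^{-12}]} before the logarithm, and the L2 term
#' summing squared weights only (biases excluded).
#'
#' @param params An [mlp_init()] object.
#' @param X Input matrix (samples x features).
#' @param Y One-hot target matrix (samples x classes).
#' @param lambda L2 penalty strength.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(params, X, Y, lambda = 0) {
  Y <- check_onehot(Y, params$layer_sizes[length(params$layer_sizes)])
  p <- pmin(pmax(mlp_forward(params, X)$probs, EPS_CLIP), 1 - EPS_CLIP)
  m <- nrow(as.matrix(X))
  reg <- if (lambda > 0) {
    lambda / (2 * m) * sum(vapply(params$weights,
                                  function(w) sum(w^2), numeric(1)))
  } else 0
  -sum(Y * log(p)) + reg
}

#' Analytic gradients of the cross-entropy loss
#'
#' Backpropagation through the softmax head: the output-layer error
#' simplifies to \eqn{\hat y - y}; hidden layers propagate through the
#' sigmoid derivative \eqn{a(1-a)}. The L2 term contributes
#' \eqn{(\lambda/m)\theta} to each weight gradient.
#'
#' @inheritParams cross_entropy_loss
#' @return List with `weights` and `biases` gradient lists shaped like
#'   the parameters.
#' @export
mlp_gradients <- function(params, X, Y, lambda = 0) {
  X <- as.matrix(X)
  Y <- check_onehot(Y, params$layer_sizes[length(params$layer_sizes)])
  fw <- mlp_forward(params, X)
  L <- length(params$weights)
  m <- nrow(X)
  gw <- vector("list", L); gb <- vector("list", L)
  delta <- fw$probs - Y                      # softmax + cross-entropy
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) X else fw$hidden[[l - 1L]]
    gw[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (lambda > 0) gw[[l]] <- gw[[l]] + lambda / m * params$weights[[l]]
    if (l > 1L) {
      h <- fw$hidden[[l - 1L]]
      delta <- (delta %*% t(params$weights[[l]])) * h * (1 - h)
    }
  }
  list(weights = gw, biases = gb)
}

flatten_params <- function(params) {
  unlist(c(lapply(seq_along(params$weights), function(l) {
    c(as.vector(params$weights[[l]]), params$biases[[l]])
  })), use.names = FALSE)
}

unflatten_params <- function(params, theta) {
  pos <- 0L
  for (l in seq_along(params$weights)) {
    nw <- length(params$weights[[l]])
    params$weights[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(params$biases[[l]])
    params$biases[[l]] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  params
}

flatten_grads <- function(g) {
  unlist(c(lapply(seq_along(g$weights), function(l) {
    c(as.vector(g$weights[[l]]), g$biases[[l]])
  })), use.names = FALSE)
}

#' Full-batch gradient descent on the cross-entropy objective
#'
#' \eqn{\theta \leftarrow \theta - \eta \nabla J(\theta)} on the whole
#' training batch each iteration; stops at `max_iters` or when the loss
#' change drops below `tol`. The loss trace is not guaranteed monotone.
#'
#' @param params An [mlp_init()] object.
#' @param X Input matrix.
#' @param Y One-hot target matrix.
#' @param config A [train_config()] with objective `"cross_entropy_gd"`.
#' @return List with `params` (trained), `trace` (cross-entropy per
#'   iteration, starting with the initial loss), `sse_trace` (squared
#'   error \eqn{\frac12\sum(\hat y - y)^2} of the softmax head per
#'   iteration, comparable across trainers) and `iters`.
#' @export
train_gd <- function(params, X, Y, config) {
  stopifnot(inherits(config, "train_config"))
  if (config$objective != "cross_entropy_gd") {
    stop("config objective must be `cross_entropy_gd`", call. = FALSE)
  }
  X <- as.matrix(X)
  loss <- cross_entropy_loss(params, X, Y, config$lambda)
  sse <- 0.5 * sum((mlp_forward(params, X)$probs - Y)^2)
  trace <- numeric(config$max_iters + 1L); trace[1L] <- loss
  sse_trace <- numeric(config$max_iters + 1L); sse_trace[1L] <- sse
  it <- 0L
  while (it < config$max_iters) {
    it <- it + 1L
    g <- mlp_gradients(params, X, Y, config$lambda)
    for (l in seq_along(params$weights)) {
      params$weights[[l]] <- params$weights[[l]] -
        config$learning_rate * g$weights[[l]]
      params$biases[[l]] <- params$biases[[l]] -
        config$learning_rate * g$biases[[l]]
    }
    new_loss <- cross_entropy_loss(params, X, Y, config$lambda)
    if (!is.finite(new_loss)) {
      stop("gradient descent diverged at iteration ", it, call. = FALSE)
    }
    trace[it + 1L] <- new_loss
    sse_trace[it + 1L] <- 0.5 * sum((mlp_forward(params, X)$probs - Y)^2)
    if (abs(loss - new_loss) < config$tol) { loss <- new_loss; break }
    loss <- new_loss
  }
  list(params = params, trace = trace[seq_len(it + 1L)],
       sse_trace = sse_trace[seq_len(it + 1L)], iters = it)
}

#' Sum-squared-error loss with sigmoid outputs
#'
#' \eqn{E = \frac12 \sum_i \sum_k (d_{ik} - y_{ik})^2} with \eqn{y} the
#' sigmoid output activations — the residual objective minimized by the
#' Levenberg-Marquardt trainer.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar loss.
#' @export
sse_loss <- function(params, X, Y) {
  Y <- check_targets01(Y, params$layer_sizes[length(params$layer_sizes)])
  0.5 * sum((Y - mlp_forward(params, X)$sigout)^2)
}

# Residuals e = d - y (stacked sample-major: rows n*K, sample varies
# fastest within an output block) and the Jacobian J = d e / d theta,
# assembled with batched linear algebra (one block of rows per output
# unit). Only networks with a single hidden layer use the fast path;
# deeper networks fall back to per-sample reverse passes.
lm_jacobian <- function(params, X, Y) {
  X <- as.matrix(X)
  Y <- check_targets01(Y, params$layer_sizes[length(params$layer_sizes)])
  fw <- mlp_forward(params, X)
  yhat <- fw$sigout
  n <- nrow(X); K <- ncol(Y); W <- n_params(params)
  e <- as.vector(Y - yhat)          # column-major: all samples for out 1, ...
  L <- length(params$weights)
  J <- matrix(0, n * K, W)
  if (L == 2L) {
    H <- fw$hidden[[1L]]
    nh <- ncol(H); ni <- ncol(X)
    gout <- yhat * (1 - yhat)       # sigmoid derivative at the output
    # parameter layout: W1 (ni*nh, col-major), b1 (nh), W2 (nh*K), b2 (K)
    off_b1 <- ni * nh
    off_w2 <- off_b1 + nh
    off_b2 <- off_w2 + nh * K
    hp <- H * (1 - H)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n + seq_len(n)
      g <- gout[, k]
      # d e_k / d W2[, k'] is nonzero only for k' = k
      J[rows, off_w2 + (k - 1L) * nh + seq_len(nh)] <- -g * H
      J[rows, off_b2 + k] <- -g
      D <- (g * hp) * rep(params$weights[[2L]][, k], each = n)  # n x nh
      # d e_k / d W1[i, j] = -D[, j] * X[, i]
      J[rows, seq_len(ni * nh)] <-
        -D[, rep(seq_len(nh), each = ni), drop = FALSE] *
         X[, rep(seq_len(ni), times = nh), drop = FALSE]
      J[rows, off_b1 + seq_len(nh)] <- -D
    }
  } else {
    for (i in seq_len(n)) {
      ji <- sample_jacobian(params, X[i, , drop = FALSE])
      for (k in seq_len(K)) J[(k - 1L) * n + i, ] <- ji[k, ]
    }
  }
  list(J = J, e = e, loss = 0.5 * sum(e^2))
}

# Reverse-mode Jacobian of the residual vector for one sample (general
# depth): row k is d e_k / d theta = -d y_k / d theta.
sample_jacobian <- function(params, x) {
  fw <- mlp_forward(params, x)
  L <- length(params$weights)
  K <- ncol(fw$logits)
  yhat <- fw$sigout
  out <- matrix(0, K, n_params(params))
  for (k in seq_len(K)) {
    gw <- vector("list", L); gb <- vector("list", L)
    delta <- matrix(0, 1L, K)
    delta[1L, k] <- yhat[1L, k] * (1 - yhat[1L, k])
    for (l in rev(seq_len(L))) {
      a_prev <- if (l == 1L) x else fw$hidden[[l - 1L]]
      gw[[l]] <- crossprod(a_prev, delta)
      gb[[l]] <- as.vector(delta)
      if (l > 1L) {
        h <- fw$hidden[[l - 1L]]
        delta <- (delta %*% t(params$weights[[l]])) * h * (1 - h)
      }
    }
    out[k, ] <- -flatten_grads(list(weights = gw, biases = gb))
  }
  out
}

#' One Levenberg-Marquardt step
#'
#' Solves \eqn{(J^\top J + \mu I)\,\Delta = -J^\top e} as a linear system
#' (never an explicit inverse) and returns the candidate parameters
#' \eqn{\theta + \Delta}. With \eqn{\mu \to 0} this is the Gauss-Newton
#' step; with large \eqn{\mu} it approaches a small gradient-descent step
#' \eqn{-(1/\mu) J^\top e}.
#'
#' @param params An [mlp_init()] object.
#' @param J Residual Jacobian (rows = samples x outputs, columns =
#'   parameters).
#' @param e Residual vector `d - y`.
#' @param mu Damping parameter (>= 0).
#' @return Candidate `mlp` parameters.
#' @export
lm_step <- function(params, J, e, mu) {
  W <- ncol(J)
  A <- crossprod(J) + diag(mu, W)
  delta <- tryCatch(solve(A, -crossprod(J, e)),
                    error = function(err) {
                      stop("LM system singular at mu = ", mu, call. = FALSE)
                    })
  unflatten_params(params, flatten_params(params) + as.vector(delta))
}

MU_MAX <- 1e12

#' Levenberg-Marquardt training on the sum-squared-error objective
#'
#' Each iteration assembles the residual Jacobian, proposes an
#' [lm_step()]; if the candidate lowers the SSE it is accepted and the
#' damping is divided by `mu_factor`, otherwise the damping is multiplied
#' and the step retried. Stops at `max_iters`, when an accepted
#' improvement falls below `tol`, or (with a warning status) when the
#' damping exceeds `1e12` without an acceptable step. The accepted-step
#' loss trace is strictly decreasing by construction.
#'
#' @param params An [mlp_init()] object.
#' @param X Input matrix.
#' @param Y One-hot target matrix.
#' @param config A [train_config()] with objective `"sse_lm"`.
#' @return List with `params`, `trace` (SSE after each accepted step,
#'   starting from the initial SSE), `iters` (accepted steps) and
#'   `status` (`"converged"`, `"max_iters"` or `"mu_overflow"`).
#' @export
train_lm <- function(params, X, Y, config) {
  stopifnot(inherits(config, "train_config"))
  if (config$objective != "sse_lm") {
    stop("config objective must be `sse_lm`", call. = FALSE)
  }
  X <- as.matrix(X)
  mu <- config$mu0
  state <- lm_jacobian(params, X, Y)
  trace <- state$loss
  it <- 0L
  status <- "max_iters"
  while (it < config$max_iters) {
    if (sqrt(sum(crossprod(state$J, state$e)^2)) < ZERO_TOL) {
      status <- "converged"; break   # zero gradient: nothing to improve
    }
    accepted <- FALSE
    while (mu <= MU_MAX) {
      # a numerically singular system (mu driven very small after many
      # accepted steps) counts as a rejected step: re-damp and retry
      cand <- tryCatch(lm_step(params, state$J, state$e, mu),
                       error = function(e) NULL)
      cand_loss <- if (is.null(cand)) NA_real_ else sse_loss(cand, X, Y)
      if (is.finite(cand_loss) && cand_loss < state$loss) {
        params <- cand
        mu <- max(mu / config$mu_factor, 1e-12)
        accepted <- TRUE
        break
      }
      mu <- mu * config$mu_factor
    }
    if (!accepted) { status <- "mu_overflow"; break }
    it <- it + 1L
    new_state <- lm_jacobian(params, X, Y)
    improvement <- state$loss - new_state$loss
    state <- new_state
    trace <- c(trace, state$loss)
    if (improvement < config$tol) { status <- "converged"; break }
  }
  list(params = params, trace = trace, iters = it, status = status)
}
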