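test_that("initialization is deterministic with zero biases and correct W", {
  a <- mlp_init(c(2, 2, 2), seed = 5)
  b <- mlp_init(c(2, 2, 2), seed = 5)
  expect_identical(a, b)
  expect_true(all(vapply(a$biases, function(x) all(x == 0), logical(1))))
  expect_equal(n_params(mlp_init(c(2, 3, 2))), 17)
  expect_error(mlp_init(c(2, 2)), "layers")
})

test_that("softmax is stable, normalized and permutation-equivariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1, 0)), c(0.731058578630005, 0.268941421369995),
               tolerance = 1e-12)
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)

  v <- c(0.3, -1.2, 2.5, 0)
  perm <- c(3, 1, 4, 2)
  expect_equal(softmax(v)[perm], softmax(v[perm]), tolerance = 1e-12)
  expect_equal(sum(softmax(v)), 1, tolerance = 1e-12)
  expect_error(softmax(numeric(0)), "empty")
})

test_that("the forward pass applies sigmoid hidden units and both heads", {
  p <- mlp_init(c(2, 3, 2), seed = 1)
  for (l in seq_along(p$weights)) p$weights[[l]][] <- 0
  fw <- mlp_forward(p, rbind(c(1, -1)))
  expect_equal(unname(fw$hidden[[1]][1, ]), rep(0.5, 3))
  expect_equal(unname(fw$probs[1, ]), c(0.5, 0.5))

  p2 <- mlp_init(c(2, 4, 3), seed = 2)
  X <- matrix(rnorm(10), 5, 2)
  fw2 <- mlp_forward(p2, X)
  expect_true(all(fw2$hidden[[1]] > 0 & fw2$hidden[[1]] < 1))
  expect_equal(rowSums(fw2$probs), rep(1, 5), tolerance = 1e-12)

  # batching consistency: identical rows give identical outputs
  fw3 <- mlp_forward(p2, X[c(1, 1, 1), ])
  expect_equal(fw3$probs[2, ], fw3$probs[1, ])
  expect_error(mlp_forward(p2, matrix(0, 2, 3)), "width")
})

test_that("cross-entropy loss matches closed forms and decomposes in lambda", {
  p <- mlp_init(c(2, 3, 2), seed = 3)
  for (l in seq_along(p$weights)) p$weights[[l]][] <- 0
  X <- matrix(rnorm(8), 4, 2)
  Y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2)
  # uniform predictions over 2 classes: loss = m * ln 2
  expect_equal(cross_entropy_loss(p, X, Y, lambda = 0), 4 * log(2),
               tolerance = 1e-12)

  p2 <- mlp_init(c(2, 3, 2), seed = 3)
  l0 <- cross_entropy_loss(p2, X, Y, lambda = 0)
  l1 <- cross_entropy_loss(p2, X, Y, lambda = 0.7)
  sum_sq <- sum(vapply(p2$weights, function(w) sum(w^2), numeric(1)))
  expect_equal(l1 - l0, 0.7 / (2 * 4) * sum_sq, tolerance = 1e-12)

  expect_error(cross_entropy_loss(p2, X, Y * 2), "one-hot")
})

test_that("analytic gradients match central finite differences", {
  p <- mlp_init(c(2, 3, 2), seed = 11)
  X <- with_seed_test(4, matrix(rnorm(16), 8, 2))
  y <- with_seed_test(5, sample(1:2, 8, TRUE))
  Y <- matrix(0, 8, 2); Y[cbind(1:8, y)] <- 1
  lambda <- 0.1
  g <- flatten_grads(mlp_gradients(p, X, Y, lambda))
  theta <- flatten_params(p)
  h <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (cross_entropy_loss(unflatten_params(p, tp), X, Y, lambda) -
       cross_entropy_loss(unflatten_params(p, tm), X, Y, lambda)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-5)
})

test_that("gradient descent reduces the XOR loss and is reproducible", {
  xor <- fixture_xor()
  p <- mlp_init(c(2, 2, 2), seed = 7)
  cfg <- train_config("cross_entropy_gd", learning_rate = 0.5,
                      max_iters = 500, tol = 0, seed = 7)
  fit <- train_gd(p, xor$X, xor$Y, cfg)
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])

  fit2 <- train_gd(p, xor$X, xor$Y, cfg)
  expect_identical(fit$trace, fit2$trace)

  null_cfg <- train_config("cross_entropy_gd", learning_rate = 0,
                           max_iters = 5, tol = 0)
  fit0 <- train_gd(p, xor$X, xor$Y, null_cfg)
  expect_equal(fit0$params, p)
})

test_that("sse loss matches hand values and adds over batches", {
  p <- mlp_init(c(2, 2, 1), seed = 1)
  X <- matrix(rnorm(6), 3, 2)
  Y <- matrix(c(1, 0, 1), 3, 1)
  y <- mlp_forward(p, X)$sigout
  expect_equal(sse_loss(p, X, Y), 0.5 * sum((Y - y)^2), tolerance = 1e-12)
  expect_equal(sse_loss(p, X[1, , drop = FALSE], Y[1, , drop = FALSE]) +
                 sse_loss(p, X[2:3, ], Y[2:3, , drop = FALSE]),
               sse_loss(p, X, Y), tolerance = 1e-12)
  # single output, d = 1, y = 0.5 -> 0.125
  p0 <- p; for (l in 1:2) p0$weights[[l]][] <- 0
  expect_equal(sse_loss(p0, X[1, , drop = FALSE],
                        matrix(1, 1, 1)), 0.125, tolerance = 1e-12)
})

test_that("LM Jacobian matches finite differences of the residuals", {
  p <- mlp_init(c(2, 3, 2), seed = 13)
  X <- with_seed_test(6, matrix(rnorm(12), 6, 2))
  y <- with_seed_test(7, sample(1:2, 6, TRUE))
  Y <- matrix(0, 6, 2); Y[cbind(1:6, y)] <- 1
  st <- lm_jacobian(p, X, Y)
  theta <- flatten_params(p)
  h <- 1e-6
  res_at <- function(th) {
    as.vector(Y - mlp_forward(unflatten_params(p, th), X)$sigout)
  }
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (res_at(tp) - res_at(tm)) / (2 * h)
  }, numeric(length(st$e)))
  expect_lt(max(abs(st$J - num)) / max(abs(num)), 1e-5)
  expect_equal(st$loss, 0.5 * sum(st$e^2), tolerance = 1e-12)
  expect_equal(nrow(st$J), 6 * 2)
})

test_that("the deep-network Jacobian fallback agrees with the fast path", {
  # two hidden layers exercise the per-sample reverse-mode assembly
  p <- mlp_init(c(2, 3, 3, 2), seed = 17)
  X <- with_seed_test(8, matrix(rnorm(8), 4, 2))
  Y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2)
  st <- lm_jacobian(p, X, Y)
  theta <- flatten_params(p)
  h <- 1e-6
  res_at <- function(th) {
    as.vector(Y - mlp_forward(unflatten_params(p, th), X)$sigout)
  }
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (res_at(tp) - res_at(tm)) / (2 * h)
  }, numeric(length(st$e)))
  expect_lt(max(abs(st$J - num)) / max(abs(num)), 1e-5)
})

test_that("one undamped LM step solves a linear least-squares residual", {
  # residuals e = y - A theta are linear in theta, so the mu = 0 step
  # (pure Gauss-Newton) lands on the least-squares optimum from any start
  p <- mlp_init(c(1, 1, 1), seed = 1)   # carrier: 4 parameters
  W <- n_params(p)
  A <- with_seed_test(33, matrix(rnorm(6 * W), 6, W))
  theta_star <- c(2, -1, 0.5, 3)
  y <- A %*% theta_star
  theta0 <- rep(-5, W)
  e0 <- as.vector(y - A %*% theta0)
  cand <- lm_step(unflatten_params(p, theta0), J = -A, e = e0, mu = 0)
  expect_equal(flatten_params(cand), theta_star, tolerance = 1e-9)
})

test_that("heavily damped LM steps align with the gradient direction", {
  p <- mlp_init(c(2, 3, 2), seed = 19)
  X <- with_seed_test(10, matrix(rnorm(12), 6, 2))
  y <- with_seed_test(11, sample(1:2, 6, TRUE))
  Y <- matrix(0, 6, 2); Y[cbind(1:6, y)] <- 1
  st <- lm_jacobian(p, X, Y)
  cand <- lm_step(p, st$J, st$e, mu = 1e12)
  delta <- flatten_params(cand) - flatten_params(p)
  grad_dir <- -as.vector(crossprod(st$J, st$e))
  cosine <- sum(delta * grad_dir) /
    sqrt(sum(delta^2)) / sqrt(sum(grad_dir^2))
  expect_gte(cosine, 0.999)
  expect_length(delta, n_params(p))
})

test_that("LM training solves XOR with a strictly decreasing trace", {
  # a 2-2-2 sigmoid network has well-known local minima on XOR, so not
  # every initialization reaches a near-zero SSE; most do
  xor <- fixture_xor()
  solved <- 0
  for (seed in 1:10) {
    p <- mlp_init(c(2, 2, 2), seed = seed)
    fit <- train_lm(p, xor$X, xor$Y,
                    train_config("sse_lm", max_iters = 200, tol = 0,
                                 seed = seed))
    expect_true(all(diff(fit$trace) < 0))
    if (min(fit$trace) < 0.01) solved <- solved + 1
  }
  expect_gte(solved, 6)
})

test_that("a zero-residual start converges immediately", {
  xor <- fixture_xor()
  p <- mlp_init(c(2, 2, 2), seed = 3)
  fit <- train_lm(p, xor$X, xor$Y, train_config("sse_lm", max_iters = 50))
  refit <- train_lm(fit$params, xor$X, xor$Y,
                    train_config("sse_lm", max_iters = 50, tol = 1e-9))
  # restarting from the fitted point improves (almost) nothing
  expect_lte(refit$iters, 2)
})
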