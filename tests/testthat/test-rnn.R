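test_that("gru_step with all-zero parameters and state returns zeros", {
  E <- 6
  p <- list(
    Wr = matrix(0, E, E), Ur = matrix(0, E, E), br = numeric(E),
    Wh = matrix(0, E, E), Uh = matrix(0, E, E), bh = numeric(E),
    Wz = matrix(0, E, E), Uz = matrix(0, E, E), bz = numeric(E),
    Wb = matrix(0, E, E), bb = numeric(E)
  )
  out <- gru_step(rnorm(E), numeric(E), p)
  expect_equal(as.numeric(out$h), numeric(E))
  expect_equal(as.numeric(out$beta), numeric(E))
})

test_that("gru_step matches the elementwise oracle on random instances", {
  for (case in 1:20) {
    E <- sample(2:8, 1)
    p <- random_gru_params(E, seed = 100 + case)
    e <- with_seed_test(200 + case, rnorm(E))
    h_prev <- with_seed_test(300 + case, rnorm(E))
    out <- gru_step(e, h_prev, p)
    ref <- gru_oracle(e, h_prev, p)
    expect_lt(max(abs(as.numeric(out$h) - ref$h)), 1e-6)
    expect_lt(max(abs(as.numeric(out$beta) - ref$beta)), 1e-6)
  }
})

test_that("gru_step with zero recurrence reduces algebraically", {
  E <- 5
  p <- random_gru_params(E, seed = 9)
  p$Ur <- p$Uh <- p$Uz <- matrix(0, E, E)
  e <- with_seed_test(10, rnorm(E))
  out <- gru_step(e, numeric(E), p)
  z <- 1 / (1 + exp(-(p$Wz %*% e + p$bz)))
  expected <- (1 - z) * tanh(p$Wh %*% e + p$bh)
  expect_lt(max(abs(out$h - expected)), 1e-10)
  expect_error(gru_step(rnorm(E), rnorm(E + 1), p), "shape")
})

test_that("rnn_forward reduces to the bias on all-zero input", {
  model <- init_rnn(K = 7, L = 3, embed_dim = 5, dropout_rate = 0, seed = 4)
  tr <- rnn_forward(matrix(0, 3, 7), numeric(3), model)
  expect_equal(tr$yhat_net, model$params$b)
  expect_true(all(tr$ct == 0))
})

test_that("the attention trace satisfies its algebraic identities", {
  model <- init_rnn(K = 9, L = 2, embed_dim = 6, dropout_rate = 0, seed = 5)
  x_t <- with_seed_test(11, matrix(rpois(4 * 9, 1), 4, 9))
  x_s <- c(1.2, -0.5)
  tr <- rnn_forward(x_t, x_s, model)
  # c = sum_t c^t + e^NT exactly
  expect_equal(tr$c, rowSums(tr$ct) + tr$e_nt, tolerance = 1e-12)
  # yhat = w . c + b exactly
  expect_equal(tr$yhat_net, sum(model$params$w * tr$c) + model$params$b,
               tolerance = 1e-12)
  # attention bounded by the tanh range
  expect_true(all(abs(tr$alpha) < 1))
  expect_true(all(abs(tr$beta) < 1))
  # inference is deterministic
  tr2 <- rnn_forward(x_t, x_s, model)
  expect_identical(tr$yhat, tr2$yhat)
  expect_error(rnn_forward(x_t[0, , drop = FALSE], x_s, model), "period")
})

test_that("analytic gradients match central finite differences", {
  set.seed(51)
  E <- 4; K <- 5; L <- 2; T_ <- 3; n <- 4
  model <- init_rnn(K, L, embed_dim = E, dropout_rate = 0, seed = 6)
  Xt <- lapply(seq_len(T_), function(t) matrix(rnorm(n * K), n, K))
  Xs <- matrix(rnorm(n * L), n, L)
  y <- rnorm(n)
  params <- model$params
  loss_of <- function(p) {
    mean((claimscast:::rnn_forward_batch(p, Xt, Xs)$yhat - y)^2)
  }
  fwd <- claimscast:::rnn_forward_batch(params, Xt, Xs)
  gr <- claimscast:::rnn_backward_batch(params, Xt, Xs, fwd,
                                        2 * (fwd$yhat - y) / n)
  modify <- function(p, path, i, d) {
    if (length(path) == 1) {
      p[[path]][i] <- p[[path]][i] + d
      p
    } else {
      p[[path[1]]] <- modify(p[[path[1]]], path[-1], i, d)
      p
    }
  }
  eps <- 1e-5
  paths <- c(
    list("Wt", "Wnt", "w", "b"),
    lapply(c("Wr", "Uh", "bh", "Wb", "bb"), function(x) c("beta_cell", x)),
    lapply(c("Uz", "Wh", "wa", "ba"), function(x) c("alpha_cell", x))
  )
  for (path in paths) {
    g <- gr
    v <- params
    for (nm in path) {
      g <- g[[nm]]
      v <- v[[nm]]
    }
    idx <- if (length(v) > 5) sample(seq_along(v), 5) else seq_along(v)
    for (i in idx) {
      num <- (loss_of(modify(params, path, i, eps)) -
                loss_of(modify(params, path, i, -eps))) / (2 * eps)
      expect_lt(abs(num - g[i]), 1e-7)
    }
  }
})

test_that("zero epochs returns the seeded initialization unchanged", {
  fx <- dense_fixture()
  m0 <- train_rnn(fx$seq_data, y = fx$y, epochs = 0, seed = 3,
                  embed_dim = 8, dropout_rate = 0)
  ref <- init_rnn(fx$K, fx$L, embed_dim = 8, dropout_rate = 0, seed = 3)
  expect_identical(m0$params, ref$params)
  # scaling is still learned from the data
  expect_false(all(m0$scaling$sd_temporal == 1))
})

test_that("training reduces loss below the variance of the target", {
  fx <- dense_fixture()
  m <- train_rnn(fx$seq_data, y = fx$y, epochs = 20, seed = 3,
                 embed_dim = 8, dropout_rate = 0, batch_size = 64)
  expect_true(all(is.finite(m$loss_history)))
  expect_lt(tail(m$loss_history, 1), head(m$loss_history, 1))
  pred <- predict(m, fx$seq_data)
  # better than the mean predictor on the training data
  expect_lt(mean((fx$y - pred)^2), var(fx$y))
})

test_that("training approaches the noise-free ceiling on planted data", {
  set.seed(52)
  n <- 1200; K <- 30
  X <- matrix(rpois(n * K, 0.6), n, K)
  beta <- numeric(K)
  beta[1:8] <- runif(8, 0.5, 1.5) * sample(c(-1, 1), 8, TRUE)
  signal <- as.numeric(X %*% beta)
  y <- 5 + signal + rnorm(n, 0, 0.5 * sd(signal))
  ceiling_r2 <- var(signal) / var(y)
  dat <- list(x_temporal = list(Matrix::Matrix(X, sparse = TRUE)),
              x_static = matrix(0, n, 0))
  m <- train_rnn(dat, y = y, epochs = 30, seed = 4, embed_dim = 16,
                 dropout_rate = 0)
  r2 <- r_squared(y, predict(m, dat))
  expect_gte(r2, 0.9 * ceiling_r2)
})

test_that("training with a fixed seed is reproducible", {
  fx <- dense_fixture()
  m1 <- train_rnn(fx$seq_data, y = fx$y, epochs = 3, seed = 8,
                  embed_dim = 6, dropout_rate = 0.5, batch_size = 64)
  m2 <- train_rnn(fx$seq_data, y = fx$y, epochs = 3, seed = 8,
                  embed_dim = 6, dropout_rate = 0.5, batch_size = 64)
  expect_identical(m1$params, m2$params)
})
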