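test_that("linear contributions are products and conserve exactly", {
  model <- structure(
    list(theta = 3, intercept = 1, col_names = "x1"),
    class = c("hc_lm", "hc_linear")
  )
  cs <- linear_contributions(model, 2)
  expect_equal(cs$contributions$contribution, 6)
  expect_equal(cs$prediction, 7)
  # zero input, zero contribution
  expect_equal(linear_contributions(model, 0)$contributions$contribution, 0)
  expect_error(linear_contributions(model, c(1, 2)), "length")

  fx <- dense_fixture()
  fit <- fit_ols(fx$X, fx$y)
  preds <- predict(fit, fx$X)
  for (i in c(3, 100, 250)) {
    cs <- linear_contributions(fit, fx$X[i, ])
    expect_equal(sum(cs$contributions$contribution) + cs$intercept,
                 preds[i], tolerance = 1e-10)
  }
})

test_that("tree-path contributions follow the gain-proportional rule", {
  # hand-built tree: root split on feature 5 (gain 3), then feature 2
  # (gain 1); leaf weight 0.8 must split 0.6 / 0.2
  tree <- data.frame(
    id = 1:5,
    is_leaf = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    feature = c(5L, 2L, NA, NA, NA),
    threshold = c(0.5, 0.5, NA, NA, NA),
    gain = c(3, 1, 0, 0, 0),
    left = c(2L, 3L, NA, NA, NA),
    right = c(5L, 4L, NA, NA, NA),
    value = c(NA, NA, 0.8, -1, 2)
  )
  model <- structure(
    list(trees = list(tree), base_score = 0.1, shrinkage = 1,
         col_names = NULL),
    class = "hc_gbm"
  )
  cs <- tree_path_contributions(model, c(0, 0, 0, 0, 0))  # left, left
  cc <- cs$contributions$contribution
  expect_equal(cc[5], 0.6)
  expect_equal(cc[2], 0.2)
  expect_equal(cs$prediction, 0.8 + 0.1)

  # single-feature tree: all weight on that feature
  cs2 <- tree_path_contributions(model, c(0, 9, 0, 0, 9))  # right path
  expect_equal(cs2$contributions$contribution[5], 2)
  expect_equal(sum(cs2$contributions$contribution[-5]), 0)
})

test_that("tree contributions conserve for a fitted ensemble", {
  fx <- dense_fixture()
  fit <- fit_gbm(fx$X, fx$y, n_rounds = 30, depth_grid = 3,
                 shrinkage_grid = 0.2)
  preds <- predict(fit, fx$X)
  for (i in seq(1, fx$n, by = 23)) {
    cs <- tree_path_contributions(fit, fx$X[i, ])
    expect_equal(cs$prediction, preds[i], tolerance = 1e-9)
  }
})

test_that("network contributions are exact and local", {
  fx <- dense_fixture()
  m <- train_rnn(fx$seq_data, y = fx$y, epochs = 8, seed = 2,
                 embed_dim = 8, dropout_rate = 0)
  preds <- predict(m, fx$seq_data)
  for (i in c(1, 50, 200)) {
    x_t <- matrix(fx$X_t[i, ], 1)
    tr <- rnn_forward(x_t, fx$X_s[i, ], m)
    cs <- rnn_contributions(m, tr, x_t, fx$X_s[i, ])
    expect_equal(cs$prediction, preds[i], tolerance = 1e-6)
    # zero inputs carry zero contribution
    zero_vars <- which(c(fx$X_t[i, ], fx$X_s[i, ]) == 0)
    expect_true(all(cs$contributions$contribution[zero_vars] == 0))
  }
  # all-zero input: prediction reduces to the intercept term
  x0 <- matrix(0, 1, fx$K)
  tr0 <- rnn_forward(x0, rep(0, fx$L), m)
  cs0 <- rnn_contributions(m, tr0, x0, rep(0, fx$L))
  expect_true(all(cs0$contributions$contribution == 0))
  expect_equal(cs0$prediction, cs0$intercept)
  # single nonzero input: its contribution is the whole signal
  x1 <- matrix(0, 1, fx$K)
  x1[1, 4] <- 3
  tr1 <- rnn_forward(x1, rep(0, fx$L), m)
  cs1 <- rnn_contributions(m, tr1, x1, rep(0, fx$L))
  nz <- cs1$contributions$contribution[cs1$contributions$variable == "t1_k4"]
  expect_equal(nz, tr1$yhat - cs1$intercept, tolerance = 1e-8)
})

test_that("unused inputs do not perturb other contributions", {
  # linear model with a zero coefficient
  fx <- dense_fixture()
  fit <- fit_ols(fx$X[, 1:6], fx$y)
  fit$theta[3] <- 0
  row <- fx$X[10, 1:6]
  c1 <- linear_contributions(fit, row)
  row2 <- row
  row2[3] <- row2[3] + 100
  c2 <- linear_contributions(fit, row2)
  expect_equal(c1$contributions$contribution[-3],
               c2$contributions$contribution[-3])
  # gbm: a feature the ensemble never split on
  g <- fit_gbm(fx$X[, 1:4], fx$y, n_rounds = 10, depth_grid = 2,
               shrinkage_grid = 0.3)
  used <- unique(unlist(lapply(g$trees, function(t) t$feature)))
  unused <- setdiff(1:4, used)
  if (length(unused)) {
    r1 <- fx$X[5, 1:4]
    r2 <- r1
    r2[unused[1]] <- r2[unused[1]] + 50
    expect_equal(tree_path_contributions(g, r1)$contributions$contribution,
                 tree_path_contributions(g, r2)$contributions$contribution)
  }
})

test_that("gain-weighted path totals rank a single-signal feature first", {
  set.seed(61)
  n <- 250
  X <- matrix(rpois(n * 6, 1), n, 6)
  y <- 3 * X[, 4] + rnorm(n, 0, 0.2)
  fit <- fit_gbm(X, y, n_rounds = 20, depth_grid = 2, shrinkage_grid = 0.3)
  totals <- rowSums(vapply(seq(1, n, by = 5), function(i) {
    abs(tree_path_contributions(fit, X[i, ])$contributions$contribution)
  }, numeric(6)))
  expect_identical(which.max(totals), 4L)
})

test_that("bootstrap stability reports the configured resamples", {
  fx <- dense_fixture()
  fit_fun <- function(x, y, idx) fit_ols(x[idx, , drop = FALSE], y[idx])
  attr_fun <- function(model, r) linear_contributions(model, fx$X[r, ])
  rep_ <- bootstrap_stability(fit_fun, attr_fun, fx$X, fx$y,
                              probe_rows = c(2, 9), n_resamples = 10,
                              seed = 3)
  expect_identical(rep_$n_resamples, 10L)
  expect_identical(length(rep_$resamples), 10L)
  expect_true(all(rep_$variables$sd_contribution >= 0))
  expect_error(
    bootstrap_stability(fit_fun, attr_fun, fx$X, fx$y, 1, n_resamples = 1),
    "at least 2"
  )
})

test_that("identity resampling of a deterministic fit has zero spread", {
  fx <- dense_fixture()
  fit_fun <- function(x, y, idx) fit_ols(x[idx, , drop = FALSE], y[idx])
  attr_fun <- function(model, r) linear_contributions(model, fx$X[r, ])
  rep_ <- bootstrap_stability(fit_fun, attr_fun, fx$X, fx$y,
                              probe_rows = 5, n_resamples = 3, seed = 1,
                              resample = "identity")
  expect_equal(max(rep_$variables$sd_contribution), 0)
  expect_equal(max(rep_$predictions$sd_prediction), 0)
})
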