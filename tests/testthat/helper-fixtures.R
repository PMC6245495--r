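# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# small persistent panel with two cohorts, quarterly-friendly window
small_panel <- function() {
  fixture("small_panel", function() {
    simulate_population(generator_config(
      n_patients = 400, n_months = 12, seed = 42, rho = 0.8,
      cohort_prevalences = c(diabetes = 0.12, copd = 0.06)
    ))
  })
}

small_period_data <- function(length_months = 3L) {
  key <- paste0("small_pd_", length_months)
  fixture(key, function() {
    panel <- small_panel()
    grid <- period_grid(panel$config$n_months, length_months)
    compute_objectives(aggregate_period(
      panel$claims, panel$enrollment, panel$demographics, grid, panel$maps
    ))
  })
}

# dense regression fixture with temporal + static blocks, used by the model
# and attribution tests
dense_fixture <- function() {
  fixture("dense_fixture", function() {
    set.seed(77)
    n <- 300L
    K <- 12L
    L <- 4L
    X_t <- matrix(rpois(n * K, 0.8), n, K)
    X_s <- cbind(matrix(rnorm(n * (L - 1)), n, L - 1),
                 rbinom(n, 1, 0.3))
    y <- 1.5 * X_t[, 2] - X_t[, 5] + 0.4 * X_s[, 1] + rnorm(n, 0, 0.5)
    list(
      X = cbind(X_t, X_s), X_t = X_t, X_s = X_s, y = y, n = n, K = K, L = L,
      seq_data = list(
        x_temporal = list(Matrix::Matrix(X_t, sparse = TRUE)),
        x_static = X_s
      )
    )
  })
}

random_gru_params <- function(E, seed) {
  with_seed_test(seed, {
    rmat <- function() matrix(rnorm(E * E, 0, 0.4), E, E)
    list(
      Wr = rmat(), Ur = rmat(), br = rnorm(E, 0, 0.2),
      Wh = rmat(), Uh = rmat(), bh = rnorm(E, 0, 0.2),
      Wz = rmat(), Uz = rmat(), bz = rnorm(E, 0, 0.2),
      Wb = rmat(), bb = rnorm(E, 0, 0.2)
    )
  })
}

# independent elementwise recomputation of the GRU update rules, written
# with scalar loops so it shares nothing with the implementation
gru_oracle <- function(e, h_prev, p) {
  E <- length(e)
  r <- hh <- z <- h <- beta <- numeric(E)
  for (i in seq_len(E)) {
    r[i] <- 1 / (1 + exp(-(sum(p$Wr[i, ] * e) + sum(p$Ur[i, ] * h_prev) +
                             p$br[i])))
  }
  for (i in seq_len(E)) {
    hh[i] <- tanh(sum(p$Wh[i, ] * e) +
                    r[i] * sum(p$Uh[i, ] * h_prev) + p$bh[i])
  }
  for (i in seq_len(E)) {
    z[i] <- 1 / (1 + exp(-(sum(p$Wz[i, ] * e) + sum(p$Uz[i, ] * h_prev) +
                             p$bz[i])))
    h[i] <- z[i] * h_prev[i] + (1 - z[i]) * hh[i]
  }
  for (i in seq_len(E)) {
    beta[i] <- tanh(sum(p$Wb[i, ] * h) + p$bb[i])
  }
  list(h = h, beta = beta)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
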