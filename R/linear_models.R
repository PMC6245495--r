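# Linear forecasters: ordinary least squares and L1-regularized regression
# fit by cyclic coordinate descent with a 10-fold cross-validated penalty.

design_matrix_of <- function(design) {
  if (inherits(design, "claims_design")) design$x else design
}

design_target_of <- function(design, y) {
  if (!is.null(y)) return(y)
  if (inherits(design, "claims_design")) design$y else
    stop("target vector required", call. = FALSE)
}

#' Ordinary least squares
#'
#' Minimizes squared error with an intercept. Rank-deficient designs
#' (constant or collinear columns) are handled by the minimum-norm solution
#' via an eigendecomposition of the centered cross-product matrix.
#'
#' @param design A `claims_design` or a numeric/sparse matrix.
#' @param y Target vector (taken from the design when omitted).
#' @return Object of class `hc_lm` with `theta` (per design column) and
#'   `intercept`.
#' @export
fit_ols <- function(design, y = NULL) {
  X <- design_matrix_of(design)
  y <- design_target_of(design, y)
  if (nrow(X) == 0L) stop("empty design", call. = FALSE)
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  p <- ncol(X)
  n <- nrow(X)
  cm <- as.numeric(Matrix::colMeans(X))
  ybar <- mean(y)
  yc <- y - ybar
  if (p <= n) {
    # centered normal equations; minimum-norm pseudoinverse for the
    # rank-deficient case
    XtX <- as.matrix(Matrix::crossprod(X)) - n * tcrossprod(cm)
    Xty <- as.numeric(Matrix::crossprod(X, y)) - n * cm * ybar
    eg <- eigen(XtX, symmetric = TRUE)
    tol <- max(eg$values, 0) * p * .Machine$double.eps
    pos <- eg$values > tol
    theta <- if (any(pos)) {
      eg$vectors[, pos, drop = FALSE] %*%
        ((t(eg$vectors[, pos, drop = FALSE]) %*% Xty) / eg$values[pos])
    } else {
      matrix(0, p, 1)
    }
    theta <- as.numeric(theta)
  } else {
    # wide design: the same minimum-norm solution through the n x n dual
    # Gram, theta = Xc' (Xc Xc')^+ yc, without densifying the centered X
    G <- as.matrix(Matrix::tcrossprod(X))
    v <- as.numeric(X %*% cm)
    Gc <- G - outer(v, rep(1, n)) - outer(rep(1, n), v) + sum(cm^2)
    eg <- eigen(Gc, symmetric = TRUE)
    tol <- max(eg$values, 0) * n * .Machine$double.eps
    pos <- eg$values > tol
    alpha <- if (any(pos)) {
      eg$vectors[, pos, drop = FALSE] %*%
        ((t(eg$vectors[, pos, drop = FALSE]) %*% yc) / eg$values[pos])
    } else {
      matrix(0, n, 1)
    }
    alpha <- as.numeric(alpha)
    theta <- as.numeric(Matrix::crossprod(X, alpha)) - cm * sum(alpha)
  }
  structure(
    list(theta = theta, intercept = ybar - sum(cm * theta),
         col_names = colnames(X)),
    class = c("hc_lm", "hc_linear")
  )
}

#' @export
predict.hc_lm <- function(object, newdata, ...) {
  X <- design_matrix_of(newdata)
  as.numeric(X %*% object$theta) + object$intercept
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Coordinate descent for (1/n) * ||y - X theta||^2 + beta * ||theta||_1 on
# internally standardized columns. Covariance updates with a lazily grown
# active set keep high-dimensional sparse designs cheap.
cd_lasso_path <- function(X, y, penalties, tol = 1e-7, max_iter = 1000L) {
  n <- nrow(X)
  p <- ncol(X)
  cm <- as.numeric(Matrix::colMeans(X))
  csd <- sqrt(pmax(
    as.numeric(Matrix::colMeans(X^2)) - cm^2, 0
  ))
  active_ok <- csd > 1e-12
  s <- ifelse(active_ok, csd, 1)
  yc <- y - mean(y)
  # <x_j_std, y_c> / n
  xy <- (as.numeric(Matrix::crossprod(X, yc)) / n - cm * mean(yc)) / s
  xy[!active_ok] <- 0

  # cached standardized gram columns, built on demand
  gram <- new.env(parent = emptyenv())
  gram_col <- function(j) {
    key <- as.character(j)
    g <- gram[[key]]
    if (is.null(g)) {
      raw <- as.numeric(Matrix::crossprod(X, X[, j])) / n
      g <- (raw - cm * cm[j]) / (s * s[j])
      g[!active_ok] <- 0
      gram[[key]] <- g
    }
    g
  }

  theta <- numeric(p)
  out <- vector("list", length(penalties))
  for (pi in seq_along(penalties)) {
    beta <- penalties[pi]
    thr <- beta / 2
    repeat {
      # strong candidate set: current actives plus coords violating KKT
      grad0 <- xy
      if (any(theta != 0)) {
        nz <- which(theta != 0)
        for (j in nz) grad0 <- grad0 - gram_col(j) * theta[j]
      }
      cand <- union(which(theta != 0), which(abs(grad0) > thr))
      cand <- cand[active_ok[cand]]
      if (!length(cand)) break
      # cyclic CD on the candidate set
      for (iter in seq_len(max_iter)) {
        delta_max <- 0
        for (j in cand) {
          gj <- gram_col(j)
          rho_j <- xy[j] - sum(gj[cand] * theta[cand]) + theta[j]
          new_t <- soft_threshold(rho_j, thr)
          d <- new_t - theta[j]
          if (d != 0) {
            theta[j] <- new_t
            delta_max <- max(delta_max, abs(d))
          }
        }
        if (delta_max < tol) break
      }
      # KKT check over all coordinates
      grad <- xy
      nz <- which(theta != 0)
      for (j in nz) grad <- grad - gram_col(j) * theta[j]
      viol <- which(abs(grad) > thr + 1e-9 & theta == 0 & active_ok)
      if (!length(viol)) break
    }
    out[[pi]] <- theta
  }
  list(thetas = out, col_means = cm, col_sds = s, active_ok = active_ok,
       y_mean = mean(y))
}

#' L1-regularized regression (coordinate descent, 10-fold CV)
#'
#' Minimizes `(1/n) * sum((y - X theta)^2) + beta * ||theta||_1` on
#' internally standardized columns (mean 0, sd 1; target centered), by
#' cyclic coordinate descent with soft-thresholding, warm starts along a
#' decreasing penalty path, and an active-set strategy. The penalty is
#' chosen at the minimum of 10-fold cross-validated squared error;
#' coefficients are reported on the original scale. Standardization
#' statistics come from the training data only.
#'
#' @param design A `claims_design` or matrix.
#' @param y Target vector (taken from the design when omitted).
#' @param penalty_grid Decreasing penalty path; defaults to `n_penalties`
#'   log-spaced values from the smallest all-zero penalty down to
#'   `penalty_min_ratio` times it.
#' @param n_penalties,penalty_min_ratio Length and depth of the default
#'   penalty path.
#' @param n_folds Cross-validation folds (10 as the reference protocol).
#' @param penalty Optional fixed penalty: skips CV.
#' @param seed Seed for the fold assignment.
#' @param tol Coordinate-change convergence tolerance.
#' @return Object of class `hc_lasso`: `theta`, `intercept`, `penalty`,
#'   `cv_path` (data.frame penalty / cv_mse / nonzero), `path` (coefficients
#'   along the penalty grid, standardized scale).
#' @export
fit_lasso <- function(design, y = NULL, penalty_grid = NULL, n_folds = 10L,
                      penalty = NULL, seed = 1L, tol = 1e-7,
                      n_penalties = 40L, penalty_min_ratio = 1e-3) {
  X <- design_matrix_of(design)
  y <- design_target_of(design, y)
  if (!all(is.finite(y))) stop("non-finite target", call. = FALSE)
  n <- nrow(X)
  stopifnot(n == length(y))

  cm <- as.numeric(Matrix::colMeans(X))
  csd <- sqrt(pmax(as.numeric(Matrix::colMeans(X^2)) - cm^2, 0))
  s <- ifelse(csd > 1e-12, csd, 1)
  yc <- y - mean(y)
  xy_abs <- abs((as.numeric(Matrix::crossprod(X, yc)) / n) / s)
  xy_abs[csd <= 1e-12] <- 0
  beta_max <- 2 * max(xy_abs, 1e-12)

  if (is.null(penalty_grid)) {
    penalty_grid <- exp(seq(log(beta_max), log(beta_max * penalty_min_ratio),
                            length.out = n_penalties))
  }
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)

  cv_path <- NULL
  if (is.null(penalty)) {
    folds <- with_seed(child_seed(seed, "cv"), {
      sample(rep_len(seq_len(n_folds), n))
    })
    cv_mse <- matrix(NA_real_, n_folds, length(penalty_grid))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit_f <- cd_lasso_path(X[tr, , drop = FALSE], y[tr], penalty_grid,
                             tol = tol)
      Xte <- X[!tr, , drop = FALSE]
      yte <- y[!tr]
      for (pi in seq_along(penalty_grid)) {
        th_std <- fit_f$thetas[[pi]]
        th <- th_std / fit_f$col_sds
        ic <- fit_f$y_mean - sum(fit_f$col_means * th)
        pred <- as.numeric(Xte %*% th) + ic
        cv_mse[f, pi] <- mean((yte - pred)^2)
      }
    }
    mse_mean <- colMeans(cv_mse)
    penalty <- penalty_grid[which.min(mse_mean)]
    cv_path <- data.frame(penalty = penalty_grid, cv_mse = mse_mean)
  }

  # final fit on all data along the path down to the chosen penalty
  path_pens <- unique(sort(c(penalty_grid[penalty_grid >= penalty], penalty),
                           decreasing = TRUE))
  fit <- cd_lasso_path(X, y, path_pens, tol = tol)
  th_std <- fit$thetas[[length(path_pens)]]
  theta <- th_std / fit$col_sds
  theta[!fit$active_ok] <- 0
  intercept <- fit$y_mean - sum(fit$col_means * theta)

  if (!is.null(cv_path)) {
    nz <- vapply(seq_along(path_pens), function(i)
      sum(fit$thetas[[i]] != 0), integer(1))
    cv_path$nonzero <- nz[match(cv_path$penalty, path_pens)]
  }

  structure(
    list(theta = theta, intercept = intercept, penalty = penalty,
         cv_path = cv_path,
         path = list(penalties = path_pens, thetas_std = fit$thetas),
         col_names = colnames(X)),
    class = c("hc_lasso", "hc_linear")
  )
}

#' @export
predict.hc_lasso <- function(object, newdata, ...) {
  X <- design_matrix_of(newdata)
  as.numeric(X %*% object$theta) + object$intercept
}
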