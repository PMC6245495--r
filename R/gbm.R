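# Second-order gradient-boosted regression trees, grown greedily from the
# regularized gain with per-leaf weights w_j = -G_j / (H_j + lambda). Under
# squared-error loss (1/2)*(yhat - y)^2 the working derivatives are
# g_i = yhat_i - y_i and h_i = 1.

# one tree as a data.frame of nodes:
#   id, is_leaf, feature, threshold, gain, left, right, value
grow_tree <- function(X_get, n_features, idx, g, h, lambda, gamma,
                      max_depth, min_obs = 2L) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L

  build <- function(idx, depth) {
    G <- sum(g[idx])
    H <- sum(h[idx])
    leaf_value <- -G / (H + lambda)
    id <- new_node()
    nodes[[id]] <<- data.frame(
      id = id, is_leaf = TRUE, feature = NA_integer_,
      threshold = NA_real_, gain = 0, left = NA_integer_,
      right = NA_integer_, value = leaf_value
    )
    if (depth >= max_depth || length(idx) < min_obs) return(id)

    best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
    parent_score <- G^2 / (H + lambda)
    for (j in seq_len(n_features)) {
      v <- X_get(idx, j)
      if (all(v == v[1])) next
      o <- order(v)
      vo <- v[o]
      gcs <- cumsum(g[idx][o])
      hcs <- cumsum(h[idx][o])
      nidx <- length(idx)
      splitable <- which(vo[-nidx] < vo[-1])
      if (!length(splitable)) next
      GL <- gcs[splitable]
      HL <- hcs[splitable]
      GR <- G - GL
      HR <- H - HL
      gains <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                        parent_score)
      b <- which.max(gains)
      # strict improvement over the current best keeps ties at the lowest
      # feature index and, within a feature, the first (lowest) threshold
      if (gains[b] > best$gain + 1e-12) {
        best <- list(
          gain = gains[b], feature = j,
          threshold = (vo[splitable[b]] + vo[splitable[b] + 1L]) / 2
        )
      }
    }
    if (is.na(best$feature) || best$gain <= gamma) return(id)

    v <- X_get(idx, best$feature)
    left_idx <- idx[v <= best$threshold]
    right_idx <- idx[v > best$threshold]
    left_id <- build(left_idx, depth + 1L)
    right_id <- build(right_idx, depth + 1L)
    nodes[[id]]$is_leaf <<- FALSE
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$gain <<- best$gain
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    nodes[[id]]$value <<- NA_real_
    id
  }
  build(idx, 0L)
  do.call(rbind, nodes)
}

predict_tree <- function(tree, X_get, idx) {
  out <- numeric(length(idx))
  assign_node <- function(rows, node_id) {
    node <- tree[node_id, ]
    if (node$is_leaf) {
      out[rows] <<- node$value
      return(invisible())
    }
    v <- X_get(idx[rows], node$feature)
    left <- rows[v <= node$threshold]
    right <- rows[v > node$threshold]
    if (length(left)) assign_node(left, node$left)
    if (length(right)) assign_node(right, node$right)
  }
  assign_node(seq_along(idx), 1L)
  out
}

gbm_core <- function(X, y, n_rounds, max_depth, shrinkage, lambda, gamma,
                     track_loss = TRUE) {
  n <- nrow(X)
  dense_cols <- new.env(parent = emptyenv())
  X_get <- function(idx, j) {
    key <- as.character(j)
    col <- dense_cols[[key]]
    if (is.null(col)) {
      col <- as.numeric(X[, j])
      dense_cols[[key]] <- col
    }
    col[idx]
  }
  # only non-constant columns can split
  keep <- which(vapply(seq_len(ncol(X)), function(j) {
    col <- as.numeric(X[, j])
    any(col != col[1])
  }, logical(1)))
  X_get_k <- function(idx, jk) X_get(idx, keep[jk])

  base_score <- mean(y)
  pred <- rep(base_score, n)
  trees <- vector("list", n_rounds)
  loss <- numeric(n_rounds)
  all_idx <- seq_len(n)
  for (r in seq_len(n_rounds)) {
    g <- pred - y
    h <- rep(1, n)
    tree <- grow_tree(X_get_k, length(keep), all_idx, g, h, lambda, gamma,
                      max_depth)
    # store original feature indices
    tree$feature <- ifelse(is.na(tree$feature), NA_integer_,
                           keep[tree$feature])
    trees[[r]] <- tree
    pred <- pred + shrinkage * predict_tree(tree, X_get, all_idx)
    if (track_loss) loss[r] <- mean((pred - y)^2)
  }
  list(trees = trees, base_score = base_score, loss = loss, pred = pred)
}

#' Gradient-boosted regression trees
#'
#' Fits an additive ensemble: each round grows one tree greedily on the
#' second-order gain
#' `0.5 * (G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda))`,
#' accepting a split only when the gain exceeds `gamma`; leaf weights are
#' `-G/(H+lambda)` scaled by the learning rate. The base score is the
#' training-target mean. When `depth_grid` or `shrinkage_grid` has more
#' than one value, hyperparameters are chosen by grid search under 5-fold
#' cross-validation.
#'
#' @param design A `claims_design` or matrix.
#' @param y Target (taken from the design when omitted).
#' @param n_rounds Number of trees (1000 in the reference protocol).
#' @param depth_grid Candidate maximum depths.
#' @param shrinkage_grid Candidate learning rates.
#' @param lambda L2 leaf-weight regularizer.
#' @param gamma Minimum gain to accept a split.
#' @param n_folds CV folds for the grid search.
#' @param seed Seed for the fold assignment.
#' @return Object of class `hc_gbm`: `trees` (list of node tables),
#'   `base_score`, `shrinkage`, `max_depth`, `lambda`, `gamma`,
#'   `train_loss`, `cv_table` (when a grid search ran).
#' @export
fit_gbm <- function(design, y = NULL, n_rounds = 1000L, depth_grid = 3L,
                    shrinkage_grid = 0.1, lambda = 1, gamma = 0,
                    n_folds = 5L, seed = 1L) {
  X <- design_matrix_of(design)
  y <- design_target_of(design, y)
  stopifnot(nrow(X) == length(y), nrow(X) > 0)
  if (!length(depth_grid) || !length(shrinkage_grid)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }

  grid <- expand.grid(depth = depth_grid, shrinkage = shrinkage_grid)
  cv_table <- NULL
  if (nrow(grid) > 1L) {
    folds <- with_seed(child_seed(seed, "cv"), {
      sample(rep_len(seq_len(n_folds), nrow(X)))
    })
    grid$cv_mse <- NA_real_
    for (gi in seq_len(nrow(grid))) {
      errs <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit_f <- gbm_core(X[tr, , drop = FALSE], y[tr], n_rounds,
                          grid$depth[gi], grid$shrinkage[gi], lambda, gamma,
                          track_loss = FALSE)
        model_f <- structure(
          list(trees = fit_f$trees, base_score = fit_f$base_score,
               shrinkage = grid$shrinkage[gi]),
          class = "hc_gbm"
        )
        pred <- predict(model_f, X[!tr, , drop = FALSE])
        errs[f] <- mean((y[!tr] - pred)^2)
      }
      grid$cv_mse[gi] <- mean(errs)
    }
    cv_table <- grid
    best <- grid[which.min(grid$cv_mse), ]
  } else {
    best <- grid[1, ]
  }

  fit <- gbm_core(X, y, n_rounds, best$depth, best$shrinkage, lambda, gamma)
  structure(
    list(trees = fit$trees, base_score = fit$base_score,
         shrinkage = best$shrinkage, max_depth = best$depth,
         lambda = lambda, gamma = gamma, train_loss = fit$loss,
         cv_table = cv_table, col_names = colnames(X)),
    class = "hc_gbm"
  )
}

#' @export
predict.hc_gbm <- function(object, newdata, ...) {
  X <- design_matrix_of(newdata)
  n <- nrow(X)
  dense_cols <- new.env(parent = emptyenv())
  X_get <- function(idx, j) {
    key <- as.character(j)
    col <- dense_cols[[key]]
    if (is.null(col)) {
      col <- as.numeric(X[, j])
      dense_cols[[key]] <- col
    }
    col[idx]
  }
  pred <- rep(object$base_score, n)
  for (tree in object$trees) {
    pred <- pred + object$shrinkage * predict_tree(tree, X_get, seq_len(n))
  }
  pred
}
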