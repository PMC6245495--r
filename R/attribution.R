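# Per-prediction decomposition into additive per-variable contributions,
# for every model family, plus bootstrap stability of those contributions
# under refitting.

contribution_set <- function(variable, contribution, intercept, prediction,
                             period = NA_integer_) {
  structure(
    list(
      contributions = data.frame(
        variable = variable,
        period = period,
        contribution = contribution,
        stringsAsFactors = FALSE
      ),
      intercept = intercept,
      prediction = prediction
    ),
    class = "contribution_set"
  )
}

#' @export
print.contribution_set <- function(x, ...) {
  cat(sprintf(
    "<contribution_set> %d variables, intercept %.4g, prediction %.4g\n",
    nrow(x$contributions), x$intercept, x$prediction
  ))
  invisible(x)
}

#' Contributions of a linear model prediction
#'
#' The contribution of variable j is `theta_j * x_j` on the original input
#' scale; the intercept is reported as its own term, so contributions plus
#' intercept reproduce the prediction exactly.
#'
#' @param model An `hc_lm` or `hc_lasso`.
#' @param row Numeric vector matching the design columns.
#' @return A `contribution_set`.
#' @export
linear_contributions <- function(model, row) {
  stopifnot(inherits(model, "hc_linear"))
  row <- as.numeric(row)
  if (length(row) != length(model$theta)) {
    stop("row length does not match design columns", call. = FALSE)
  }
  contrib <- model$theta * row
  vn <- model$col_names %||% sprintf("x%d", seq_along(row))
  contribution_set(
    variable = vn, contribution = contrib,
    intercept = model$intercept,
    prediction = sum(contrib) + model$intercept
  )
}

#' Decision-path contributions of a boosted-tree prediction
#'
#' For each tree the reached leaf's shrunken weight is distributed over the
#' splitting nodes on the root-to-leaf path proportionally to each node's
#' split gain (equal shares when all gains on the path are zero) and
#' credited to the node's split feature. Trees that never split credit
#' their weight to the intercept term alongside the base score.
#' Contributions plus intercept reproduce the ensemble prediction exactly.
#'
#' @param model An `hc_gbm`.
#' @param row Numeric vector matching the design columns.
#' @return A `contribution_set`.
#' @export
tree_path_contributions <- function(model, row) {
  stopifnot(inherits(model, "hc_gbm"))
  row <- as.numeric(row)
  p <- length(row)
  contrib <- numeric(p)
  intercept <- model$base_score
  for (tree in model$trees) {
    node_id <- 1L
    path_feat <- integer(0)
    path_gain <- numeric(0)
    repeat {
      node <- tree[node_id, ]
      if (node$is_leaf) break
      if (is.na(node$left) || is.na(node$right)) {
        stop("corrupt tree: unreachable leaf", call. = FALSE)
      }
      path_feat <- c(path_feat, node$feature)
      path_gain <- c(path_gain, node$gain)
      node_id <- if (row[node$feature] <= node$threshold) node$left else
        node$right
    }
    leaf_w <- model$shrinkage * tree[node_id, "value"]
    if (!length(path_feat)) {
      intercept <- intercept + leaf_w
      next
    }
    shares <- if (sum(path_gain) > 0) {
      leaf_w * path_gain / sum(path_gain)
    } else {
      rep(leaf_w / length(path_gain), length(path_gain))
    }
    for (i in seq_along(path_feat)) {
      contrib[path_feat[i]] <- contrib[path_feat[i]] + shares[i]
    }
  }
  vn <- model$col_names %||% sprintf("x%d", seq_len(p))
  contribution_set(
    variable = vn, contribution = contrib, intercept = intercept,
    prediction = sum(contrib) + intercept
  )
}

#' Contributions of an attention-GRU prediction
#'
#' The prediction is an exact linear function of the inputs given the
#' attention weights: the contribution of temporal variable `x_tk` is
#' `x_tk * alpha_t * w . (beta_t (x) W_T[, k])` and of static variable
#' `x_l` is `x_l * w . W_NT[, l]` (both mapped back to original target
#' units); the intercept absorbs the output bias and the target
#' de-standardization. Computed with dropout off.
#'
#' @param model An `hc_rnn`.
#' @param trace A trace from [rnn_forward()] at inference for the same
#'   inputs.
#' @param x_temporal,x_static The inputs the trace was produced from
#'   (original units).
#' @return A `contribution_set` with one row per (variable, period) pair
#'   plus the static variables (period `NA`).
#' @export
rnn_contributions <- function(model, trace, x_temporal, x_static = NULL) {
  stopifnot(inherits(model, "hc_rnn"))
  x_temporal <- as.matrix(x_temporal)
  T_ <- nrow(x_temporal)
  if (length(trace$alpha) != T_) {
    stop("trace and inputs disagree on the number of periods", call. = FALSE)
  }
  sc <- model$scaling
  p <- model$params
  K <- model$K
  L <- model$L

  contribs <- list()
  for (t in seq_len(T_)) {
    # w . (beta_t (x) W_T[, k]) for all k at once
    coef_k <- as.numeric(crossprod(p$Wt, trace$beta[, t] * p$w))  # length K
    x_net <- x_temporal[t, ] / sc$sd_temporal
    contribs[[t]] <- data.frame(
      variable = sprintf("t%d_k%d", t, seq_len(K)),
      period = t,
      contribution = x_net * trace$alpha[t] * coef_k * sc$y_sd
    )
  }
  if (L > 0) {
    coef_l <- as.numeric(crossprod(p$Wnt, p$w))
    x_net <- as.numeric(x_static) / sc$sd_static
    contribs[[T_ + 1L]] <- data.frame(
      variable = sprintf("static_l%d", seq_len(L)),
      period = NA_integer_,
      contribution = x_net * coef_l * sc$y_sd
    )
  }
  tab <- do.call(rbind, contribs)
  intercept <- p$b * sc$y_sd + sc$y_mean
  structure(
    list(
      contributions = tab,
      intercept = intercept,
      prediction = sum(tab$contribution) + intercept
    ),
    class = "contribution_set"
  )
}

#' Bootstrap stability of contributions under refitting
#'
#' Resamples the training rows with replacement (at the patient level),
#' refits with the supplied procedure on each resample, attributes the same
#' probe rows every time, and reports per-variable mean and sd of the
#' contributions together with the mean and sd of the predictions.
#'
#' @param fit_fun Function `(x, y, resample_index) -> model`; must be
#'   deterministic given the resample and its own seed.
#' @param attribute_fun Function `(model, row_index) -> contribution_set`
#'   for a probe row.
#' @param x,y Training design (matrix or `claims_design`) and target.
#' @param probe_rows Integer indices of the rows to attribute.
#' @param n_resamples Number of bootstrap refits (10 in the reference
#'   protocol).
#' @param seed Seed for the resampling draws.
#' @param resample Either `"bootstrap"` or `"identity"` (degenerate; every
#'   resample is the full data — useful to isolate fit stochasticity).
#' @return Object of class `stability_report`: `variables` (data.frame
#'   with per-variable, per-probe-row mean and sd contribution),
#'   `predictions` (per-row mean and sd), `n_resamples`.
#' @export
bootstrap_stability <- function(fit_fun, attribute_fun, x, y, probe_rows,
                                n_resamples = 10L, seed = 1L,
                                resample = c("bootstrap", "identity")) {
  resample <- match.arg(resample)
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 2L) stop("need at least 2 resamples", call. = FALSE)
  n <- if (inherits(x, "claims_design")) nrow(x$x) else nrow(x)
  draws <- with_seed(child_seed(seed, "boot"), {
    lapply(seq_len(n_resamples), function(i) {
      if (resample == "identity") seq_len(n) else
        sample.int(n, n, replace = TRUE)
    })
  })
  per_rep <- vector("list", n_resamples)
  preds <- matrix(NA_real_, n_resamples, length(probe_rows))
  for (i in seq_len(n_resamples)) {
    model <- fit_fun(x, y, draws[[i]])
    sets <- lapply(probe_rows, function(r) attribute_fun(model, r))
    preds[i, ] <- vapply(sets, function(s) s$prediction, numeric(1))
    per_rep[[i]] <- do.call(rbind, lapply(seq_along(sets), function(ri) {
      d <- sets[[ri]]$contributions
      d$probe_row <- probe_rows[ri]
      d$resample <- i
      d
    }))
  }
  all_c <- do.call(rbind, per_rep)
  # static variables carry period NA; recode to 0 so they survive grouping
  all_c$period[is.na(all_c$period)] <- 0L
  agg <- stats::aggregate(
    contribution ~ variable + period + probe_row, data = all_c,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  variables <- data.frame(
    variable = agg$variable, period = agg$period, probe_row = agg$probe_row,
    mean_contribution = agg$contribution[, "mean"],
    sd_contribution = agg$contribution[, "sd"]
  )
  structure(
    list(
      variables = variables,
      predictions = data.frame(
        probe_row = probe_rows,
        mean_prediction = colMeans(preds),
        sd_prediction = apply(preds, 2, stats::sd)
      ),
      n_resamples = n_resamples,
      resamples = draws
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d resamples, %d probe rows, %d variables\n",
    x$n_resamples, nrow(x$predictions),
    length(unique(x$variables$variable))
  ))
  invisible(x)
}
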