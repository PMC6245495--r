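# JSON save / load for every model family, so attributions can be computed
# without the training environment.

#' Save a fitted model as a JSON parameter container
#'
#' Serializes the parameters of an `hc_lm`, `hc_lasso`, `hc_gbm` or
#' `hc_rnn` (trees and weight matrices written out explicitly) to a JSON
#' file readable by [load_model()].
#'
#' @param model A fitted model object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cls <- intersect(class(model), c("hc_lm", "hc_lasso", "hc_gbm", "hc_rnn"))
  if (!length(cls)) stop("unsupported model class", call. = FALSE)
  payload <- switch(cls[1],
    hc_lm = list(theta = model$theta, intercept = model$intercept,
                 col_names = model$col_names),
    hc_lasso = list(theta = model$theta, intercept = model$intercept,
                    penalty = model$penalty, col_names = model$col_names),
    hc_gbm = list(
      # leaves carry NA feature/threshold/children: encode as -1 sentinels
      # so the JSON stays plain numeric arrays
      trees = lapply(model$trees, function(tr) list(
        id = tr$id,
        is_leaf = as.integer(tr$is_leaf),
        feature = ifelse(is.na(tr$feature), -1L, tr$feature),
        threshold = ifelse(is.na(tr$threshold), 0, tr$threshold),
        gain = tr$gain,
        left = ifelse(is.na(tr$left), -1L, tr$left),
        right = ifelse(is.na(tr$right), -1L, tr$right),
        value = ifelse(is.na(tr$value), 0, tr$value)
      )),
      base_score = model$base_score, shrinkage = model$shrinkage,
      max_depth = model$max_depth, lambda = model$lambda,
      gamma = model$gamma, col_names = model$col_names
    ),
    hc_rnn = list(
      params = model$params, E = model$E, K = model$K, L = model$L,
      dropout_rate = model$dropout_rate, scaling = model$scaling
    )
  )
  jsonlite::write_json(
    list(class = cls[1], payload = payload), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

relist_matrix <- function(x) {
  if (is.list(x)) do.call(rbind, lapply(x, unlist)) else x
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pl <- obj$payload
  switch(obj$class,
    hc_lm = structure(
      list(theta = as.numeric(pl$theta), intercept = pl$intercept,
           col_names = pl$col_names),
      class = c("hc_lm", "hc_linear")
    ),
    hc_lasso = structure(
      list(theta = as.numeric(pl$theta), intercept = pl$intercept,
           penalty = pl$penalty, cv_path = NULL, path = NULL,
           col_names = pl$col_names),
      class = c("hc_lasso", "hc_linear")
    ),
    hc_gbm = structure(
      list(
        # read_json transposes the tree list into per-field column lists
        # (or matrices when every tree has the same node count)
        trees = lapply(seq_len(if (is.matrix(pl$trees$id))
          nrow(pl$trees$id) else length(pl$trees$id)), function(i) {
          fld <- function(nm) {
            x <- pl$trees[[nm]]
            if (is.matrix(x)) x[i, ] else unlist(x[[i]])
          }
          is_leaf <- as.logical(as.integer(fld("is_leaf")))
          un_sentinel <- function(v) {
            v <- as.numeric(v)
            v[is_leaf] <- NA
            v
          }
          data.frame(
            id = as.integer(fld("id")), is_leaf = is_leaf,
            feature = as.integer(un_sentinel(fld("feature"))),
            threshold = un_sentinel(fld("threshold")),
            gain = as.numeric(fld("gain")),
            left = as.integer(un_sentinel(fld("left"))),
            right = as.integer(un_sentinel(fld("right"))),
            value = {
              v <- as.numeric(fld("value"))
              v[!is_leaf] <- NA
              v
            }
          )
        }),
        base_score = pl$base_score, shrinkage = pl$shrinkage,
        max_depth = pl$max_depth, lambda = pl$lambda, gamma = pl$gamma,
        col_names = pl$col_names
      ),
      class = "hc_gbm"
    ),
    hc_rnn = {
      p <- pl$params
      fix_cell <- function(cell) {
        for (nm in c("Wr", "Ur", "Wh", "Uh", "Wz", "Uz", "Wb")) {
          if (!is.null(cell[[nm]])) cell[[nm]] <- relist_matrix(cell[[nm]])
        }
        for (nm in c("br", "bh", "bz", "bb", "wa")) {
          if (!is.null(cell[[nm]])) cell[[nm]] <- as.numeric(cell[[nm]])
        }
        cell
      }
      p$Wt <- relist_matrix(p$Wt)
      p$Wnt <- relist_matrix(p$Wnt)
      if (is.null(dim(p$Wnt))) p$Wnt <- matrix(0, pl$E, 0)
      p$beta_cell <- fix_cell(p$beta_cell)
      p$alpha_cell <- fix_cell(p$alpha_cell)
      p$w <- as.numeric(p$w)
      structure(
        list(params = p, E = pl$E, K = pl$K, L = pl$L,
             dropout_rate = pl$dropout_rate,
             scaling = list(
               sd_temporal = as.numeric(pl$scaling$sd_temporal),
               sd_static = as.numeric(pl$scaling$sd_static),
               y_mean = pl$scaling$y_mean, y_sd = pl$scaling$y_sd
             ),
             loss_history = numeric(0)),
        class = "hc_rnn"
      )
    },
    stop("unknown model class in file", call. = FALSE)
  )
}
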