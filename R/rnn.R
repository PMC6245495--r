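# Dual-attention GRU forecaster.
#
# Each prior period's K input variables are embedded (e^t = W_T x^t), the
# statics are embedded once (e^NT = W_NT x^NT), and two independent GRU
# chains run over the embeddings in chronological order: one produces a
# per-period elementwise attention beta^t = tanh(W_b h^t + b_b), the other a
# scalar period attention alpha^t = tanh(w_a . g^t + b_a). The context
# c = sum_t alpha^t beta^t (x) e^t + e^NT is mapped to the prediction
# yhat = w . c + b. Because the recurrences only produce attention weights,
# the prediction is an exact linear function of the inputs given the
# attentions, which is what makes per-variable attribution exact.
#
# All gradients are derived by hand; training uses ADADELTA on mini-batch
# mean squared error. Dropout (inverted scaling) is applied to embedding
# and context vectors during training only.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One gated-recurrent-unit step with elementwise attention output
#'
#' Computes the reset gate `r = sigmoid(W_r e + U_r h_prev + b_r)`, the
#' candidate state `hh = tanh(W_h e + r * (U_h h_prev) + b_h)`, the update
#' gate `z = sigmoid(W_z e + U_z h_prev + b_z)`, the new hidden state
#' `h = z * h_prev + (1 - z) * hh`, and the attention vector
#' `beta = tanh(W_b h + b_b)`.
#'
#' @param e_t Embedding vector (length E) or E x n matrix of column
#'   samples.
#' @param h_prev Previous hidden state, same shape as `e_t`.
#' @param params List with `Wr, Ur, br, Wh, Uh, bh, Wz, Uz, bz, Wb, bb`.
#' @return List with `h`, `beta`, and the gate activations `r`, `hh`, `z`.
#' @export
gru_step <- function(e_t, h_prev, params) {
  e_t <- as.matrix(e_t)
  h_prev <- as.matrix(h_prev)
  if (!identical(dim(e_t), dim(h_prev))) {
    stop("e_t and h_prev shapes differ", call. = FALSE)
  }
  if (ncol(params$Wr) != nrow(e_t)) {
    stop("parameter / input shape mismatch", call. = FALSE)
  }
  r <- sigmoid(params$Wr %*% e_t + params$Ur %*% h_prev + params$br)
  hh <- tanh(params$Wh %*% e_t + r * (params$Uh %*% h_prev) + params$bh)
  z <- sigmoid(params$Wz %*% e_t + params$Uz %*% h_prev + params$bz)
  h <- z * h_prev + (1 - z) * hh
  beta <- tanh(params$Wb %*% h + params$bb)
  list(h = h, beta = beta, r = r, hh = hh, z = z)
}

# fan-in scaled uniform initialization
init_mat <- function(nr, nc, fan_in) {
  a <- sqrt(1 / max(fan_in, 1))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_cell <- function(E, with_beta_head = TRUE) {
  cell <- list(
    Wr = init_mat(E, E, E), Ur = init_mat(E, E, E), br = numeric(E),
    Wh = init_mat(E, E, E), Uh = init_mat(E, E, E), bh = numeric(E),
    Wz = init_mat(E, E, E), Uz = init_mat(E, E, E), bz = numeric(E)
  )
  if (with_beta_head) {
    cell$Wb <- init_mat(E, E, E)
    cell$bb <- numeric(E)
  }
  cell
}

#' Initialize a dual-attention GRU model
#'
#' Weights are uniform scaled by fan-in; biases start at zero except the
#' scalar attention bias `ba`, which starts at 0.5 so that early in
#' training the period attention passes temporal signal through rather
#' than starting shut.
#'
#' @param K Temporal input dimension per period.
#' @param L Static input dimension (0 allowed).
#' @param embed_dim Embedding size E (128 in the reference protocol).
#' @param dropout_rate Dropout on embedding and context vectors during
#'   training (0.5 in the reference protocol).
#' @param seed Integer seed.
#' @return Object of class `hc_rnn` with untrained parameters and identity
#'   input/target scaling.
#' @export
init_rnn <- function(K, L, embed_dim = 128L, dropout_rate = 0.5, seed = 1L) {
  E <- as.integer(embed_dim)
  params <- with_seed(child_seed(seed, "init"), {
    list(
      Wt = init_mat(E, K, K),
      Wnt = if (L > 0) init_mat(E, L, L) else matrix(0, E, 0),
      beta_cell = init_cell(E, with_beta_head = TRUE),
      alpha_cell = c(init_cell(E, with_beta_head = FALSE),
                     list(wa = as.numeric(init_mat(E, 1, E)), ba = 0.5)),
      w = as.numeric(init_mat(E, 1, E)),
      b = 0
    )
  })
  structure(
    list(
      params = params, E = E, K = as.integer(K), L = as.integer(L),
      dropout_rate = dropout_rate,
      scaling = list(sd_temporal = rep(1, K),
                     sd_static = rep(1, max(L, 0)),
                     y_mean = 0, y_sd = 1),
      loss_history = numeric(0)
    ),
    class = "hc_rnn"
  )
}

# batched forward pass; Xt: list of T (n x K) matrices already on the
# network scale, Xs: n x L matrix on the network scale. Columns of every
# cached matrix are samples. Returns caches sufficient for backprop.
rnn_forward_batch <- function(params, Xt, Xs, training = FALSE,
                              dropout_rate = 0) {
  T_ <- length(Xt)
  n <- nrow(Xt[[1]])
  E <- length(params$w)
  keep <- 1 - dropout_rate
  drop_mask <- function() {
    if (training && dropout_rate > 0) {
      matrix(stats::rbinom(E * n, 1L, keep) / keep, E, n)
    } else NULL
  }

  e <- vector("list", T_)
  masks_e <- vector("list", T_)
  for (t in seq_len(T_)) {
    et <- as.matrix(params$Wt %*% Matrix::t(Xt[[t]]))
    m <- drop_mask()
    if (!is.null(m)) et <- et * m
    e[[t]] <- et
    masks_e[t] <- list(m)   # keep NULL entries (no dropout) in place
  }
  e_nt <- if (ncol(params$Wnt) > 0) {
    as.matrix(params$Wnt %*% t(Xs))
  } else {
    matrix(0, E, n)
  }
  m_nt <- drop_mask()
  if (!is.null(m_nt)) e_nt <- e_nt * m_nt

  bc <- params$beta_cell
  ac <- params$alpha_cell
  h_prev <- matrix(0, E, n)
  g_prev <- matrix(0, E, n)
  beta <- vector("list", T_)
  alpha <- vector("list", T_)
  cache_b <- vector("list", T_)
  cache_a <- vector("list", T_)
  for (t in seq_len(T_)) {
    sb <- gru_step(e[[t]], h_prev, bc)
    sa_r <- sigmoid(ac$Wr %*% e[[t]] + ac$Ur %*% g_prev + ac$br)
    sa_hh <- tanh(ac$Wh %*% e[[t]] + sa_r * (ac$Uh %*% g_prev) + ac$bh)
    sa_z <- sigmoid(ac$Wz %*% e[[t]] + ac$Uz %*% g_prev + ac$bz)
    g <- sa_z * g_prev + (1 - sa_z) * sa_hh
    alpha_t <- tanh(as.numeric(crossprod(ac$wa, g)) + ac$ba)  # length n
    cache_b[[t]] <- c(sb, list(h_prev = h_prev))
    cache_a[[t]] <- list(r = sa_r, hh = sa_hh, z = sa_z, h = g,
                         h_prev = g_prev)
    beta[[t]] <- sb$beta
    alpha[[t]] <- alpha_t
    h_prev <- sb$h
    g_prev <- g
  }

  ct <- vector("list", T_)
  c_sum <- e_nt
  for (t in seq_len(T_)) {
    ct[[t]] <- sweep(beta[[t]] * e[[t]], 2, alpha[[t]], `*`)
    c_sum <- c_sum + ct[[t]]
  }
  m_c <- drop_mask()
  c_used <- if (!is.null(m_c)) c_sum * m_c else c_sum
  yhat <- as.numeric(crossprod(params$w, c_used)) + params$b

  list(
    e = e, e_nt = e_nt, masks_e = masks_e, mask_nt = m_nt, mask_c = m_c,
    beta = beta, alpha = alpha, cache_b = cache_b, cache_a = cache_a,
    ct = ct, c = c_sum, c_used = c_used, yhat = yhat, T_ = T_, n = n
  )
}

# batched backward pass; dy is the length-n gradient of the loss wrt yhat.
rnn_backward_batch <- function(params, Xt, Xs, fwd, dy, dropout_rate = 0) {
  E <- length(params$w)
  T_ <- fwd$T_
  n <- fwd$n
  zero_cell <- function(cell) lapply(cell, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)) * 0
  })
  g <- list(
    Wt = matrix(0, E, ncol(params$Wt)),
    Wnt = matrix(0, E, ncol(params$Wnt)),
    beta_cell = zero_cell(params$beta_cell),
    alpha_cell = zero_cell(params$alpha_cell),
    w = numeric(E), b = 0
  )

  dyr <- matrix(dy, nrow = 1)
  g$w <- as.numeric(fwd$c_used %*% dy)
  g$b <- sum(dy)
  dc_used <- params$w %*% dyr             # E x n
  dc <- if (!is.null(fwd$mask_c)) dc_used * fwd$mask_c else dc_used

  # statics
  de_nt <- dc
  if (!is.null(fwd$mask_nt)) de_nt <- de_nt  # mask already baked into e_nt
  if (ncol(params$Wnt) > 0) {
    dent_raw <- if (!is.null(fwd$mask_nt)) dc * fwd$mask_nt else dc
    g$Wnt <- as.matrix(dent_raw %*% Xs)
  }

  de <- vector("list", T_)        # gradient wrt (post-dropout) embeddings
  dh_head <- vector("list", T_)   # from the beta attention head
  dg_head <- vector("list", T_)   # from the alpha attention head
  bc <- params$beta_cell
  ac <- params$alpha_cell
  for (t in seq_len(T_)) {
    beta_t <- fwd$beta[[t]]
    alpha_t <- fwd$alpha[[t]]
    e_t <- fwd$e[[t]]
    dct <- dc
    dalpha <- colSums(dct * beta_t * e_t)           # length n
    dbeta <- sweep(dct * e_t, 2, alpha_t, `*`)
    de[[t]] <- sweep(dct * beta_t, 2, alpha_t, `*`)

    # beta head
    dpre_b <- dbeta * (1 - beta_t^2)
    h_t <- fwd$cache_b[[t]]$h
    g$beta_cell$Wb <- g$beta_cell$Wb + dpre_b %*% t(h_t)
    g$beta_cell$bb <- g$beta_cell$bb + rowSums(dpre_b)
    dh_head[[t]] <- crossprod(bc$Wb, dpre_b)

    # alpha head
    dpre_a <- dalpha * (1 - alpha_t^2)              # length n
    g_t <- fwd$cache_a[[t]]$h
    g$alpha_cell$wa <- g$alpha_cell$wa + as.numeric(g_t %*% dpre_a)
    g$alpha_cell$ba <- g$alpha_cell$ba + sum(dpre_a)
    dg_head[[t]] <- ac$wa %*% matrix(dpre_a, nrow = 1)
  }

  bptt <- function(cell, caches, d_head, grad_cell) {
    dh_next <- matrix(0, E, n)
    for (t in rev(seq_len(T_))) {
      cc <- caches[[t]]
      dh <- d_head[[t]] + dh_next
      h_prev <- cc$h_prev
      Uh_hp <- cell$Uh %*% h_prev
      dz <- dh * (h_prev - cc$hh)
      dhh <- dh * (1 - cc$z)
      dpre_hh <- dhh * (1 - cc$hh^2)
      dr <- dpre_hh * Uh_hp
      dpre_z <- dz * cc$z * (1 - cc$z)
      dpre_r <- dr * cc$r * (1 - cc$r)
      e_t <- fwd$e[[t]]

      grad_cell$Wh <- grad_cell$Wh + dpre_hh %*% t(e_t)
      grad_cell$Uh <- grad_cell$Uh + (dpre_hh * cc$r) %*% t(h_prev)
      grad_cell$bh <- grad_cell$bh + rowSums(dpre_hh)
      grad_cell$Wz <- grad_cell$Wz + dpre_z %*% t(e_t)
      grad_cell$Uz <- grad_cell$Uz + dpre_z %*% t(h_prev)
      grad_cell$bz <- grad_cell$bz + rowSums(dpre_z)
      grad_cell$Wr <- grad_cell$Wr + dpre_r %*% t(e_t)
      grad_cell$Ur <- grad_cell$Ur + dpre_r %*% t(h_prev)
      grad_cell$br <- grad_cell$br + rowSums(dpre_r)

      de[[t]] <<- de[[t]] + crossprod(cell$Wh, dpre_hh) +
        crossprod(cell$Wz, dpre_z) + crossprod(cell$Wr, dpre_r)
      dh_next <- dh * cc$z + crossprod(cell$Uh, dpre_hh * cc$r) +
        crossprod(cell$Uz, dpre_z) + crossprod(cell$Ur, dpre_r)
    }
    grad_cell
  }
  g$beta_cell[c("Wr", "Ur", "br", "Wh", "Uh", "bh", "Wz", "Uz", "bz")] <-
    bptt(bc, fwd$cache_b, dh_head, g$beta_cell)[
      c("Wr", "Ur", "br", "Wh", "Uh", "bh", "Wz", "Uz", "bz")]
  g$alpha_cell[c("Wr", "Ur", "br", "Wh", "Uh", "bh", "Wz", "Uz", "bz")] <-
    bptt(ac, fwd$cache_a, dg_head, g$alpha_cell)[
      c("Wr", "Ur", "br", "Wh", "Uh", "bh", "Wz", "Uz", "bz")]

  for (t in seq_len(T_)) {
    de_raw <- if (!is.null(fwd$masks_e[[t]])) de[[t]] * fwd$masks_e[[t]] else
      de[[t]]
    g$Wt <- g$Wt + as.matrix(de_raw %*% Xt[[t]])
  }
  g
}

#' Forward pass of the attention GRU for one patient
#'
#' Embeds the T temporal input vectors and the statics, runs the two
#' attention GRU chains oldest-to-newest, and returns the full attention
#' trace. Inputs are given in original units; the model's internal scaling
#' is applied. At inference (`training = FALSE`) the pass is a
#' deterministic pure function of inputs and parameters; dropout is active
#' only during training.
#'
#' @param x_temporal T x K matrix (one row per prior period, oldest first).
#' @param x_static Length-L vector (may be empty).
#' @param model An `hc_rnn`.
#' @param training Apply dropout?
#' @return List (the attention trace): `e` (E x T), `e_nt`, `h`, `g`
#'   (E x T hidden states), `alpha` (length T), `beta` (E x T), `ct`
#'   (E x T), `c`, `yhat_net` (network scale, equals `w . c + b` exactly)
#'   and `yhat` (original target units).
#' @export
rnn_forward <- function(x_temporal, x_static, model, training = FALSE) {
  x_temporal <- as.matrix(x_temporal)
  T_ <- nrow(x_temporal)
  if (T_ < 1L) stop("need at least one period", call. = FALSE)
  stopifnot(ncol(x_temporal) == model$K)
  if (model$L > 0 && length(x_static) != model$L) {
    stop("static input length mismatch", call. = FALSE)
  }
  sc <- model$scaling
  Xt <- lapply(seq_len(T_), function(t) {
    matrix(x_temporal[t, ] / sc$sd_temporal, nrow = 1)
  })
  Xs <- if (model$L > 0) {
    matrix(x_static / sc$sd_static, nrow = 1)
  } else {
    matrix(0, 1, 0)
  }
  fwd <- rnn_forward_batch(model$params, Xt, Xs, training = training,
                           dropout_rate = model$dropout_rate)
  grab <- function(lst, field) {
    do.call(cbind, lapply(lst, function(x) x[[field]][, 1]))
  }
  list(
    e = do.call(cbind, lapply(fwd$e, function(m) m[, 1])),
    e_nt = fwd$e_nt[, 1],
    h = grab(fwd$cache_b, "h"),
    g = grab(fwd$cache_a, "h"),
    alpha = vapply(fwd$alpha, `[`, numeric(1), 1L),
    beta = do.call(cbind, lapply(fwd$beta, function(m) m[, 1])),
    ct = do.call(cbind, lapply(fwd$ct, function(m) m[, 1])),
    c = fwd$c[, 1],
    yhat_net = fwd$yhat[1],
    yhat = fwd$yhat[1] * sc$y_sd + sc$y_mean
  )
}

# prepare network-scale sequence data from a claims_design (or raw lists)
rnn_prepare <- function(design, y = NULL, need_y = TRUE) {
  if (inherits(design, "claims_design")) {
    seqs <- design_sequences(design)
    if (need_y) y <- design_target_of(design, y)
    list(Xt = seqs$x_temporal, Xs = seqs$x_static, y = y)
  } else {
    stopifnot(is.list(design), !is.null(design$x_temporal))
    list(Xt = design$x_temporal,
         Xs = design$x_static %||% matrix(0, nrow(design$x_temporal[[1]]), 0),
         y = if (need_y) design_target_of(design, y) else y)
  }
}

#' Train the dual-attention GRU
#'
#' Minimizes mean squared error by mini-batch back-propagation with the
#' ADADELTA adaptive learning-rate scheme. Temporal and static columns are
#' scaled by their training-set standard deviations (no centering, so the
#' all-zero input still maps to the intercept); the target is centered and
#' scaled. With a fixed seed and single-threaded BLAS the trajectory is
#' reproducible.
#'
#' @param design A `claims_design` (or list with `x_temporal`, `x_static`).
#' @param y Target (taken from the design when omitted).
#' @param epochs Training epochs; 0 returns the initialized model.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param embed_dim Embedding size E.
#' @param dropout_rate Dropout on embeddings and context (training only).
#' @param batch_size Mini-batch size.
#' @param adadelta_rho,adadelta_eps ADADELTA decay and stabilizer.
#' @return A trained `hc_rnn` with `loss_history` (per-epoch MSE on the
#'   network scale).
#' @export
train_rnn <- function(design, y = NULL, epochs = 30L, seed = 1L,
                      embed_dim = 128L, dropout_rate = 0.5,
                      batch_size = 128L, adadelta_rho = 0.95,
                      adadelta_eps = 1e-6) {
  dat <- rnn_prepare(design, y)
  Xt <- dat$Xt
  Xs <- dat$Xs
  y <- dat$y
  stopifnot(all(is.finite(y)))
  n <- nrow(Xt[[1]])
  K <- ncol(Xt[[1]])
  L <- ncol(Xs)

  col_sd_nozero <- function(M) {
    mu2 <- as.numeric(Matrix::colMeans(M^2))
    mu <- as.numeric(Matrix::colMeans(M))
    s <- sqrt(pmax(mu2 - mu^2, 0))
    ifelse(s > 1e-12, s, 1)
  }
  sd2 <- vapply(Xt, function(M) col_sd_nozero(M)^2, numeric(K))
  if (is.null(dim(sd2))) sd2 <- matrix(sd2, nrow = K)
  sd_t <- sqrt(rowMeans(sd2))
  sd_t <- ifelse(sd_t > 1e-12, sd_t, 1)
  sd_s <- if (L > 0) col_sd_nozero(Xs) else numeric(0)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1

  Xt_s <- lapply(Xt, function(M) M %*% Matrix::Diagonal(x = 1 / sd_t))
  Xs_s <- if (L > 0) sweep(Xs, 2, sd_s, `/`) else Xs
  yn <- (y - y_mean) / y_sd

  model <- init_rnn(K, L, embed_dim = embed_dim,
                    dropout_rate = dropout_rate, seed = seed)
  model$scaling <- list(sd_temporal = sd_t, sd_static = sd_s,
                        y_mean = y_mean, y_sd = y_sd)
  if (epochs == 0L) return(model)

  params <- model$params
  acc_g <- rapply(params, function(x) x * 0, how = "replace")
  acc_d <- rapply(params, function(x) x * 0, how = "replace")

  apply_update <- function(params, grads, acc_g, acc_d) {
    walk <- function(p, g, ag, ad) {
      if (is.list(p)) {
        for (nm in names(p)) {
          res <- walk(p[[nm]], g[[nm]], ag[[nm]], ad[[nm]])
          p[[nm]] <- res$p; ag[[nm]] <- res$ag; ad[[nm]] <- res$ad
        }
        return(list(p = p, ag = ag, ad = ad))
      }
      ag <- adadelta_rho * ag + (1 - adadelta_rho) * g^2
      step <- -sqrt(ad + adadelta_eps) / sqrt(ag + adadelta_eps) * g
      ad <- adadelta_rho * ad + (1 - adadelta_rho) * step^2
      list(p = p + step, ag = ag, ad = ad)
    }
    walk(params, grads, acc_g, acc_d)
  }

  loss_history <- numeric(epochs)
  with_seed(child_seed(seed, "batch"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xt_b <- lapply(Xt_s, function(M) M[idx, , drop = FALSE])
        Xs_b <- Xs_s[idx, , drop = FALSE]
        fwd <- rnn_forward_batch(params, Xt_b, Xs_b, training = TRUE,
                                 dropout_rate = dropout_rate)
        resid <- fwd$yhat - yn[idx]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss", call. = FALSE)
        }
        batch_losses <- c(batch_losses, loss)
        dy <- 2 * resid / length(idx)
        grads <- rnn_backward_batch(params, Xt_b, Xs_b, fwd, dy,
                                    dropout_rate = dropout_rate)
        upd <- apply_update(params, grads, acc_g, acc_d)
        params <- upd$p
        acc_g <- upd$ag
        acc_d <- upd$ad
      }
      loss_history[ep] <- mean(batch_losses)
    }
  })
  model$params <- params
  model$loss_history <- loss_history
  model
}

#' @export
predict.hc_rnn <- function(object, newdata, ...) {
  dat <- rnn_prepare(newdata, need_y = FALSE)
  sc <- object$scaling
  Xt_s <- lapply(dat$Xt, function(M) {
    M %*% Matrix::Diagonal(x = 1 / sc$sd_temporal)
  })
  Xs_s <- if (object$L > 0) sweep(dat$Xs, 2, sc$sd_static, `/`) else dat$Xs
  fwd <- rnn_forward_batch(object$params, Xt_s, Xs_s, training = FALSE)
  fwd$yhat * sc$y_sd + sc$y_mean
}
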