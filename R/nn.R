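# Minimal neural-network primitives (forward + analytic backward) used by
# the sedation/delirium model: 1-D convolution (im2col + BLAS), batch
# normalization, ReLU, max pooling, dense layers, an LSTM cell unrolled
# over time, and an RMSprop optimizer. All gradients are exact and are
# verified against finite differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- conv1d (compiled kernels) ----------------------------------------

# W: out_ch x in_ch x k ; X: N x C x T ; 'same' padding, stride 1
nn_conv1d_init <- function(in_ch, out_ch, k) {
  sd <- sqrt(2 / (in_ch * k))
  list(W = array(stats::rnorm(out_ch * in_ch * k, 0, sd),
                 dim = c(out_ch, in_ch, k)),
       b = numeric(out_ch))
}

# im2col (C++) + BLAS gemm; cache keeps the unfolded input for backward
nn_conv1d_fwd <- function(p, X) {
  d <- dim(X)
  k <- dim(p$W)[3L]; O <- dim(p$W)[1L]; C <- d[2L]
  Xc <- im2col_cpp(X, d, k)
  Wm <- matrix(aperm(p$W, c(3L, 2L, 1L)), nrow = C * k)   # (C*k) x O
  out_m <- Xc %*% Wm
  out <- nt_o_to_not_cpp(out_m, d[1L], d[3L], O, p$b)
  list(out = out, cache = list(Xc = Xc, Wm = Wm, dims = d, k = k))
}

nn_conv1d_bwd <- function(p, dout, cache) {
  d <- cache$dims
  k <- cache$k; O <- dim(p$W)[1L]; C <- d[2L]
  dout_m <- not_to_nt_o_cpp(dout, dim(dout))
  dWm <- crossprod(cache$Xc, dout_m)                      # (C*k) x O
  dW <- aperm(array(dWm, dim = c(k, C, O)), c(3L, 2L, 1L))
  db <- colSums(dout_m)
  dXc <- tcrossprod(dout_m, cache$Wm)                     # (N*T) x (C*k)
  dX <- col2im_cpp(dXc, d, k)
  list(dX = dX, grads = list(W = dW, b = db))
}

## ---- batch normalization (per channel over N and T) -------------------

nn_bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

nn_bn_fwd <- function(p, X, train = TRUE, momentum = 0.9, eps = 1e-5) {
  N <- dim(X)[1L]; C <- dim(X)[2L]; T_ <- dim(X)[3L]
  if (train) {
    st <- bn_stats_cpp(X, dim(X))
    mu <- st[, 1L]
    v <- st[, 2L]
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * v
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  ap <- bn_apply_cpp(X, dim(X), mu, inv_sd, p$gamma, p$beta)
  list(out = ap$out, p = p,
       cache = list(Xhat = ap$xhat, inv_sd = inv_sd, train = train))
}

nn_bn_bwd <- function(p, dout, cache) {
  g <- bn_bwd_cpp(dout, cache$Xhat, dim(dout), cache$inv_sd, p$gamma,
                  cache$train)
  list(dX = g$dX, grads = list(gamma = g$dgamma, beta = g$dbeta))
}

## ---- relu / maxpool / global average pool -----------------------------

nn_relu_fwd <- function(X) {
  r <- relu_fwd_cpp(X)
  list(out = r$out, cache = r$mask)
}
nn_relu_bwd <- function(dout, mask) dout * mask

# width-2, stride-2 max pooling along time (odd trailing sample dropped)
nn_pool_fwd <- function(X) {
  T_ <- dim(X)[3L]
  p <- pool2_fwd_cpp(X, dim(X))
  list(out = p$out,
       cache = list(take_a = p$take_a, T_in = T_, T_out = T_ %/% 2L))
}
nn_pool_bwd <- function(dout, cache) {
  pool2_bwd_cpp(dout, cache$take_a, dim(dout), cache$T_in)
}

nn_gap_fwd <- function(X) {
  list(out = rowMeans(X, dims = 2L), cache = dim(X)[3L])
}
nn_gap_bwd <- function(dout, T_) {
  gap_bwd_cpp(dout, T_)
}

## ---- dense ------------------------------------------------------------

nn_dense_init <- function(D, M) {
  list(W = matrix(stats::rnorm(D * M, 0, sqrt(2 / D)), D, M), b = numeric(M))
}
nn_dense_fwd <- function(p, X) {
  list(out = sweep(X %*% p$W, 2L, p$b, "+"), cache = X)
}
nn_dense_bwd <- function(p, dout, X) {
  list(dX = tcrossprod(dout, p$W),
       grads = list(W = crossprod(X, dout), b = colSums(dout)))
}

## ---- LSTM -------------------------------------------------------------

# gate order in the 4H blocks: input, forget, cell, output
nn_lstm_init <- function(D, H) {
  s <- 1 / sqrt(H)
  p <- list(Wx = matrix(stats::rnorm(D * 4 * H, 0, s), D, 4 * H),
            Wh = matrix(stats::rnorm(H * 4 * H, 0, s), H, 4 * H),
            b = numeric(4 * H))
  p$b[(H + 1L):(2L * H)] <- 1       # forget-gate bias
  p
}

# X: N x T x D -> hidden states N x T x H
nn_lstm_fwd <- function(p, X) {
  N <- dim(X)[1L]; T_ <- dim(X)[2L]; D <- dim(X)[3L]
  H <- ncol(p$Wh)/ 4L
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Hs <- array(0, dim = c(N, T_, H))
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(X[, t, ], N, D)
    a <- xt %*% p$Wx + h %*% p$Wh
    a <- sweep(a, 2L, p$b, "+")
    i <- .sigmoid(a[, 1:H, drop = FALSE])
    f <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    Hs[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = Hs, cache = cache)
}

# dHs: N x T x H gradient on every hidden state
nn_lstm_bwd <- function(p, dHs, cache) {
  T_ <- length(cache)
  N <- dim(dHs)[1L]; H <- dim(dHs)[3L]
  D <- nrow(p$Wx)
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  dX <- array(0, dim = c(N, T_, D))
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- matrix(dHs[, t, ], N, H) + dh_next
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(p$Wx)
    dh_next <- da %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- RMSprop ----------------------------------------------------------

rmsprop_init <- function() list(cache = list())

# params/grads are nested lists of numeric arrays addressed by path names
.nn_flatten <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- paste0(prefix, nm)
    if (is.list(x[[nm]])) out <- c(out, .nn_flatten(x[[nm]], paste0(key, "/")))
    else out[[key]] <- x[[nm]]
  }
  out
}

.nn_assign <- function(x, key, value) {
  parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
  assign_rec <- function(node, parts, value) {
    if (length(parts) == 1L) { node[[parts]] <- value; return(node) }
    node[[parts[1L]]] <- assign_rec(node[[parts[1L]]], parts[-1L], value)
    node
  }
  assign_rec(x, parts, value)
}

rmsprop_step <- function(opt, params, grads, lr = 1e-3, rho = 0.9,
                         eps = 1e-8, skip = character(0)) {
  fp <- .nn_flatten(params); fg <- .nn_flatten(grads)
  for (key in names(fg)) {
    if (any(startsWith(key, skip))) next
    g <- fg[[key]]
    if (is.null(g)) next
    cache <- opt$cache[[key]]
    if (is.null(cache)) cache <- g * 0
    cache <- rho * cache + (1 - rho) * g^2
    opt$cache[[key]] <- cache
    fp[[key]] <- fp[[key]] - lr * g / (sqrt(cache) + eps)
  }
  for (key in names(fp)) params <- .nn_assign(params, key, fp[[key]])
  list(opt = opt, params = params)
}
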