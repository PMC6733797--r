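# Finite-difference verification of the analytic gradients that the
# staged training relies on, plus determinism/shape contracts of the
# encoder.

num_grad_at <- function(fn, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    (fn(x1) - fn(x2)) / (2 * eps)
  }, numeric(1L))
}

test_that("encoder + ordinal head gradients match finite differences", {
  set.seed(21)
  cfg <- model_config(n_blocks = 2L, kernel = 3L, filters0 = 4L,
                      double_every = 1L, pool_every = 1L,
                      lstm_hidden = 4L, transfer_M = 1L)
  enc <- eegtrack:::make_encoder(cfg)
  head <- eegtrack:::make_head(enc$D, "ordinal")
  X <- array(rnorm(4 * 2 * 16), dim = c(4, 2, 16))
  y <- c(-5L, -3L, 0L, -1L)
  w <- c(1, 2, 1, 1.5)
  params <- list(enc = enc, head = head)
  loss_fn <- function(p) {
    fw <- eegtrack:::encoder_fwd(p$enc, X, train = TRUE)
    eegtrack:::head_grad_feat(p$head, fw$emb, y, w)$loss
  }
  fw <- eegtrack:::encoder_fwd(params$enc, X, train = TRUE)
  hg <- eegtrack:::head_grad_feat(params$head, fw$emb, y, w)
  bw <- eegtrack:::encoder_bwd(params$enc, fw$cache, hg$dfeat)
  fg <- eegtrack:::.nn_flatten(list(enc = bw$grads, head = hg$grads))
  fp <- eegtrack:::.nn_flatten(params)
  for (key in c("enc/blocks/b1/conv1/W", "enc/blocks/b1/bn1/gamma",
                "enc/blocks/b2/conv2/W", "enc/blocks/b2/proj/W",
                "head/dense/W", "head/raw")) {
    pv <- fp[[key]]
    idx <- unique(pmin(length(pv), c(1L, ceiling(length(pv) / 2), length(pv))))
    num <- num_grad_at(function(v) {
      loss_fn(eegtrack:::.nn_assign(params, key, v))
    }, pv, idx)
    expect_equal(as.numeric(fg[[key]])[idx], num, tolerance = 1e-4,
                 info = key)
  }
  # gradient w.r.t. the input (saliency path), eval mode
  fwe <- eegtrack:::encoder_fwd(params$enc, X, train = FALSE)
  hge <- eegtrack:::head_grad_feat(params$head, fwe$emb, y, w)
  bwe <- eegtrack:::encoder_bwd(params$enc, fwe$cache, hge$dfeat)
  fX <- function(Xa) {
    fw <- eegtrack:::encoder_fwd(params$enc, Xa, train = FALSE)
    eegtrack:::head_grad_feat(params$head, fw$emb, y, w)$loss
  }
  idx <- c(1L, 57L, 128L)
  expect_equal(as.numeric(bwe$dX)[idx], num_grad_at(fX, X, idx),
               tolerance = 1e-4)
})

test_that("LSTM + sequence-head gradients match finite differences", {
  set.seed(22)
  D <- 3L; H <- 4L
  lstm <- eegtrack:::nn_lstm_init(D, H)
  head <- eegtrack:::make_head(H, "binary")
  X <- array(rnorm(3 * 5 * D), dim = c(3, 5, D))
  y <- c(0, 1, 1); w <- c(1, 1, 2)
  pl <- list(lstm = lstm, head = head)
  loss_fn <- function(p) {
    fw <- eegtrack:::nn_lstm_fwd(p$lstm, X)
    eegtrack:::head_grad_seq(p$head, fw$out, y, w)$loss
  }
  fw <- eegtrack:::nn_lstm_fwd(pl$lstm, X)
  hg <- eegtrack:::head_grad_seq(pl$head, fw$out, y, w)
  bw <- eegtrack:::nn_lstm_bwd(pl$lstm, hg$dH, fw$cache)
  fg <- eegtrack:::.nn_flatten(list(lstm = bw$grads, head = hg$grads))
  fp <- eegtrack:::.nn_flatten(pl)
  for (key in c("lstm/Wx", "lstm/Wh", "lstm/b", "head/dense/W")) {
    pv <- fp[[key]]
    idx <- unique(pmin(length(pv), c(2L, ceiling(length(pv) / 3), length(pv))))
    num <- num_grad_at(function(v) {
      loss_fn(eegtrack:::.nn_assign(pl, key, v))
    }, pv, idx)
    expect_equal(as.numeric(fg[[key]])[idx], num, tolerance = 1e-4,
                 info = key)
  }
  # input gradient
  fX <- function(Xa) {
    fw <- eegtrack:::nn_lstm_fwd(pl$lstm, Xa)
    eegtrack:::head_grad_seq(pl$head, fw$out, y, w)$loss
  }
  idx <- c(1L, 20L, 45L)
  expect_equal(as.numeric(bw$dX)[idx], num_grad_at(fX, X, idx),
               tolerance = 1e-4)
})

test_that("encoding is deterministic, shaped N x D, and channel-sensitive", {
  model <- blank_model(seed = 3)
  set.seed(30)
  X <- array(rnorm(6 * 2 * 32), dim = c(6, 2, 32))
  X[2, , ] <- X[1, , ]                       # duplicated segment
  emb <- encode_segments(model, X)
  expect_equal(dim(emb), c(6L, model$encoder$D))
  expect_equal(emb[1, ], emb[2, ])           # determinism in eval mode
  # channel swap changes the embedding (channels are not pooled)
  Xs <- X
  Xs[3, 1, ] <- X[3, 2, ]; Xs[3, 2, ] <- X[3, 1, ]
  emb2 <- encode_segments(model, Xs)
  expect_gt(max(abs(emb2[3, ] - emb[3, ])), 1e-8)
  expect_error(encode_segments(model, matrix(0, 2, 10)), "array")
})

test_that("RMSprop skips frozen parameter paths", {
  set.seed(31)
  params <- list(a = list(W = matrix(rnorm(4), 2)), b = list(W = matrix(rnorm(4), 2)))
  grads <- list(a = list(W = matrix(1, 2, 2)), b = list(W = matrix(1, 2, 2)))
  opt <- eegtrack:::rmsprop_init()
  st <- eegtrack:::rmsprop_step(opt, params, grads, lr = 0.1, skip = "a/")
  expect_equal(st$params$a$W, params$a$W)    # frozen: bit-identical
  expect_false(isTRUE(all.equal(st$params$b$W, params$b$W)))
})
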