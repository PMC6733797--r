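#' Model configuration
#'
#' Architecture and optimization settings for the CNN + stacked-LSTM
#' tracker. Defaults describe the full-scale architecture: 8
#' convolutional blocks of two convolutions with a max-pooling skip
#' connection, filters doubling every fourth block, two LSTM layers
#' trained in separate stages, RMSprop (lr 0.001) with minibatch 32,
#' inverse-frequency class weights, and transfer of the first 5 blocks
#' to the delirium model. [reduced_config()] gives a desk-scale variant
#' used throughout the tests.
#'
#' @param n_blocks number of convolutional blocks.
#' @param kernel temporal kernel width.
#' @param filters0 filters in the first block.
#' @param double_every double the filter count every this many blocks.
#' @param pool_every max-pool (stride 2) every this many blocks.
#' @param lstm_hidden hidden units per LSTM layer.
#' @param transfer_M CNN blocks copied and frozen for the delirium model.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param epochs integer vector of max epochs for stages 1-3.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac fraction of training windows held out for validation.
#' @param max_stage1_segments cap on training segments for stage 1.
#' @param seq_step_min stride (minutes) between 9.5-min training
#'   sequences within a 1-h window.
#' @param seed master seed for splits, initialization and batching.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_blocks = 8L, kernel = 16L, filters0 = 32L,
                         double_every = 4L, pool_every = 2L,
                         lstm_hidden = 32L, transfer_M = 5L, lr = 1e-3,
                         batch_size = 32L, epochs = c(30L, 30L, 30L),
                         patience = 10L, val_frac = 0.1,
                         max_stage1_segments = Inf, seq_step_min = 1,
                         seed = 1L) {
  stopifnot(transfer_M >= 1L, transfer_M <= n_blocks, lr > 0)
  structure(list(n_blocks = n_blocks, kernel = kernel, filters0 = filters0,
                 double_every = double_every, pool_every = pool_every,
                 lstm_hidden = lstm_hidden, transfer_M = transfer_M, lr = lr,
                 batch_size = batch_size, epochs = rep_len(epochs, 3L),
                 patience = patience, val_frac = val_frac,
                 max_stage1_segments = max_stage1_segments,
                 seq_step_min = seq_step_min, seed = seed),
            class = "model_config")
}

#' Desk-scale configuration
#'
#' A small architecture (4 blocks, 8-16 filters, kernel 8, LSTM hidden
#' 16, 2 frozen transfer blocks) with capped stage-1 data, suitable for
#' CPU-only training on synthetic cohorts.
#'
#' @param ... overrides passed to [model_config()].
#' @export
reduced_config <- function(...) {
  defaults <- list(n_blocks = 4L, kernel = 8L, filters0 = 8L,
                   double_every = 2L, pool_every = 1L, lstm_hidden = 16L,
                   transfer_M = 2L, epochs = c(8L, 25L, 60L), patience = 8L,
                   max_stage1_segments = 4000L, seq_step_min = 5)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

.block_filters <- function(config) {
  config$filters0 * 2^((seq_len(config$n_blocks) - 1L) %/% config$double_every)
}

## ---- encoder ----------------------------------------------------------

make_encoder <- function(config, in_ch = 2L) {
  filters <- .block_filters(config)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    ic <- if (b == 1L) in_ch else filters[b - 1L]
    oc <- filters[b]
    blocks[[b]] <- list(
      conv1 = nn_conv1d_init(ic, oc, config$kernel),
      bn1 = nn_bn_init(oc),
      conv2 = nn_conv1d_init(oc, oc, config$kernel),
      bn2 = nn_bn_init(oc),
      proj = if (ic != oc) nn_conv1d_init(ic, oc, 1L) else NULL,
      pool = (b %% config$pool_every) == 0L
    )
  }
  names(blocks) <- paste0("b", seq_len(config$n_blocks))
  list(blocks = blocks, D = filters[config$n_blocks])
}

# `frozen` leading blocks run in eval mode even while training, so that
# their batch-norm running statistics stay bit-identical when transferred
encoder_fwd <- function(enc, X, train = FALSE, frozen = 0L) {
  caches <- vector("list", length(enc$blocks))
  h <- X
  for (b in seq_along(enc$blocks)) {
    blk <- enc$blocks[[b]]
    tr_b <- train && b > frozen
    c1 <- nn_conv1d_fwd(blk$conv1, h)
    b1 <- nn_bn_fwd(blk$bn1, c1$out, tr_b)
    enc$blocks[[b]]$bn1 <- b1$p
    r1 <- nn_relu_fwd(b1$out)
    c2 <- nn_conv1d_fwd(blk$conv2, r1$out)
    b2 <- nn_bn_fwd(blk$bn2, c2$out, tr_b)
    enc$blocks[[b]]$bn2 <- b2$p
    if (is.null(blk$proj)) {
      skip <- h; pc <- NULL
    } else {
      pc <- nn_conv1d_fwd(blk$proj, h)
      skip <- pc$out
    }
    if (blk$pool) {
      ph <- nn_pool_fwd(b2$out); ps <- nn_pool_fwd(skip)
      summed <- ph$out + ps$out
    } else {
      ph <- NULL; ps <- NULL
      summed <- b2$out + skip
    }
    ro <- nn_relu_fwd(summed)
    caches[[b]] <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                        c2 = c2$cache, b2 = b2$cache,
                        pc = if (is.null(pc)) NULL else pc$cache,
                        ph = if (is.null(ph)) NULL else ph$cache,
                        ps = if (is.null(ps)) NULL else ps$cache,
                        ro = ro$cache)
    h <- ro$out
  }
  g <- nn_gap_fwd(h)
  list(emb = g$out, enc = enc,
       cache = list(blocks = caches, gap = g$cache))
}

encoder_bwd <- function(enc, cache, demb) {
  dh <- nn_gap_bwd(demb, cache$gap)
  grads <- list(blocks = vector("list", length(enc$blocks)))
  for (b in rev(seq_along(enc$blocks))) {
    blk <- enc$blocks[[b]]
    cc <- cache$blocks[[b]]
    dsum <- nn_relu_bwd(dh, cc$ro)
    if (blk$pool) {
      dmain <- nn_pool_bwd(dsum, cc$ph)
      dskip <- nn_pool_bwd(dsum, cc$ps)
    } else {
      dmain <- dsum; dskip <- dsum
    }
    g2 <- nn_bn_bwd(blk$bn2, dmain, cc$b2)
    gc2 <- nn_conv1d_bwd(blk$conv2, g2$dX, cc$c2)
    dr1 <- nn_relu_bwd(gc2$dX, cc$r1)
    g1 <- nn_bn_bwd(blk$bn1, dr1, cc$b1)
    gc1 <- nn_conv1d_bwd(blk$conv1, g1$dX, cc$c1)
    dh <- gc1$dX
    if (is.null(blk$proj)) {
      dh <- dh + dskip
      gproj <- NULL
    } else {
      gp <- nn_conv1d_bwd(blk$proj, dskip, cc$pc)
      dh <- dh + gp$dX
      gproj <- gp$grads
    }
    grads$blocks[[b]] <- list(conv1 = gc1$grads, bn1 = g1$grads,
                              conv2 = gc2$grads, bn2 = g2$grads,
                              proj = gproj)
  }
  names(grads$blocks) <- names(enc$blocks)
  list(dX = dh, grads = grads)
}

# embeddings for a (possibly large) segment tensor, minibatched, eval mode
encode_tensor <- function(enc, X, batch_size = 128L) {
  N <- dim(X)[1L]
  out <- matrix(0, N, enc$D)
  i <- 1L
  while (i <= N) {
    j <- min(N, i + batch_size - 1L)
    fw <- encoder_fwd(enc, X[i:j, , , drop = FALSE], train = FALSE)
    out[i:j, ] <- fw$emb
    i <- j + 1L
  }
  out
}

#' Encode 4-s segments into embeddings
#'
#' Runs the trained convolutional encoder in evaluation mode over a
#' segment batch, producing one embedding per segment (deterministic
#' given weights and input).
#'
#' @param model a `sedation_model` (or an encoder list).
#' @param batch a `segment_batch` or an N x 2 x 250 array.
#' @return N x D embedding matrix.
#' @export
encode_segments <- function(model, batch) {
  enc <- if (inherits(model, "sedation_model")) model$encoder else model
  X <- if (inherits(batch, "segment_batch")) batch$tensor else batch
  if (length(dim(X)) != 3L) stop("segments must be an N x C x T array")
  encode_tensor(enc, X)
}

## ---- output heads -----------------------------------------------------

make_head <- function(D, type = c("ordinal", "binary")) {
  type <- match.arg(type)
  h <- list(type = type, dense = nn_dense_init(D, 1L))
  if (type == "ordinal") {
    h$raw <- .raw_from_theta(stats::qlogis(seq_len(5L) / 6) * 2)
  }
  h
}

head_thresholds <- function(head) .theta_from_raw(head$raw)

# scores for a feature matrix (N x D) -> numeric N
head_score <- function(head, feat) {
  as.numeric(nn_dense_fwd(head$dense, feat)$out)
}

.binary_nll <- function(z, y, weights) {
  p <- .sigmoid(z)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  wsum <- sum(weights)
  loss <- sum(weights * -(y * log(p) + (1 - y) * log(1 - p))) / wsum
  list(loss = loss, dz = weights * (p - y) / wsum)
}

# loss + gradients for segment-level features (N x D)
head_grad_feat <- function(head, feat, y, weights) {
  fw <- nn_dense_fwd(head$dense, feat)
  z <- as.numeric(fw$out)
  if (head$type == "ordinal") {
    o <- ordinal_nll(z, y, head_thresholds(head), weights)
    dz <- o$dz; draw <- .dtheta_to_draw(o$dtheta, head$raw); loss <- o$loss
  } else {
    o <- .binary_nll(z, y, weights)
    dz <- o$dz; draw <- NULL; loss <- o$loss
  }
  dd <- nn_dense_bwd(head$dense, matrix(dz, ncol = 1L), fw$cache)
  grads <- list(dense = dd$grads)
  if (!is.null(draw)) grads$raw <- draw
  list(loss = loss, dfeat = dd$dX, grads = grads)
}

# loss + gradients for sequences (H: n x T x D); the per-step scores are
# averaged across steps before the loss, matching window-level evaluation
head_grad_seq <- function(head, H, y, weights) {
  n <- dim(H)[1L]; T_ <- dim(H)[2L]; D <- dim(H)[3L]
  flat <- matrix(aperm(H, c(1L, 2L, 3L)), nrow = n * T_)  # (n*T) x D
  fw <- nn_dense_fwd(head$dense, flat)
  zmat <- matrix(fw$out, n, T_)
  zbar <- rowMeans(zmat)
  if (head$type == "ordinal") {
    o <- ordinal_nll(zbar, y, head_thresholds(head), weights)
    dzbar <- o$dz; draw <- .dtheta_to_draw(o$dtheta, head$raw)
    loss <- o$loss
  } else {
    o <- .binary_nll(zbar, y, weights)
    dzbar <- o$dz; draw <- NULL; loss <- o$loss
  }
  dz_flat <- matrix(rep(dzbar / T_, T_), ncol = 1L)
  dd <- nn_dense_bwd(head$dense, dz_flat, fw$cache)
  dH <- array(dd$dX, dim = c(n, T_, D))
  grads <- list(dense = dd$grads)
  if (!is.null(draw)) grads$raw <- draw
  list(loss = loss, dH = dH, grads = grads)
}

## ---- data preparation -------------------------------------------------

#' Patient-grouped cross-validation folds
#'
#' Random assignment of patients to k folds; no patient appears in more
#' than one fold.
#'
#' @param patient_ids vector of patient identifiers (one per sample, or
#'   the unique ids).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of k vectors of patient ids (test set of each fold).
#' @export
grouped_folds <- function(patient_ids, k = 10L, seed = 1L) {
  ids <- unique(patient_ids)
  if (length(ids) < k) stop("fewer patients than folds")
  .with_seed(seed, {
    perm <- sample(ids)
    split(perm, rep_len(seq_len(k), length(perm)))
  })
}

#' Build model-ready assessment windows from a synthetic cohort
#'
#' For every nurse RASS assessment of every patient: extract the 1-h
#' window, filter/downsample, apply the four artifact rules to the 900
#' contiguous 4-s segments, and apply the sequence retention rule
#' (dropped when > 50% artifact). Delirium labels attach the clinical
#' convention: windows at RASS -4/-5 are delirium-positive, otherwise
#' the patient's CAM status is used.
#'
#' @param cohort a `synth_cohort`.
#' @param patients indices to include (default all).
#' @param verbose print progress.
#' @return list of windows; each holds `signal` (2 x T matrix, 62.5 Hz),
#'   `rass`, `cam`, `patient`, `time`, `mask` (artifact flags), `kept`
#'   (sequence rule).
#' @export
cohort_windows <- function(cohort, patients = NULL, verbose = FALSE) {
  if (is.null(patients)) patients <- seq_along(cohort$patients)
  out <- list()
  for (i in patients) {
    rec2 <- cohort_record(cohort, i, montage = "bipolar")
    asm <- cohort$patients[[i]]$assessments
    rass_asm <- asm[asm$kind == "RASS" & asm$rater == "nurse", ]
    for (r in seq_len(nrow(rass_asm))) {
      win <- suppressWarnings(extract_window(rec2, rass_asm$time[r]))
      win <- filter_and_resample(win)
      batch <- segment(win, mode = "contiguous")
      mask <- detect_artifacts(batch)
      kept <- filter_sequences(mask)
      rass <- rass_asm$value[r]
      out[[length(out) + 1L]] <- list(
        signal = win$data, rass = rass,
        cam = as.integer(rass <= -4L || cohort$patients[[i]]$cam_positive),
        patient = i, time = rass_asm$time[r],
        mask = mask$flags, kept = kept)
    }
    if (verbose) message("patient ", i, ": ", length(out), " windows so far")
    rm(rec2); gc(FALSE)
  }
  out
}

.window_tensor <- function(w, mode = "contiguous") {
  rec <- eeg_record(w$signal, 62.5, c("Fp1-F7", "Fp2-F8"))
  segment(rec, mode = mode)
}

## ---- staged training --------------------------------------------------

.stage_loop <- function(step_fn, val_fn, params, opt, n_train, config,
                        stage, skip = character(0)) {
  best <- list(loss = Inf, params = params)
  wait <- 0L
  history <- numeric(0)
  n_batch <- max(1L, ceiling(n_train / config$batch_size))
  for (ep in seq_len(config$epochs[stage])) {
    ord <- sample.int(n_train)
    for (bi in seq_len(n_batch)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, n_train)]
      sg <- step_fn(params, idx)
      params <- sg$params
      st <- rmsprop_step(opt, params, sg$grads, lr = config$lr, skip = skip)
      opt <- st$opt; params <- st$params
    }
    vl <- val_fn(params)
    history <- c(history, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = best$params, val_loss = best$loss, history = history)
}

# stage 1: CNN + segment-level head on artifact-free overlapping segments
.train_stage1 <- function(windows_tr, windows_va, config, task, encoder,
                          head, frozen_blocks = 0L) {
  lab_of <- function(w) if (task == "rass") w$rass else w$cam
  # sample overlapping training segments per window, drop artifacts
  per_win <- max(8L, ceiling(config$max_stage1_segments / length(windows_tr)))
  seg_list <- list(); lab <- c()
  for (w in windows_tr) {
    batch <- .window_tensor(w, "overlapping")
    n <- n_segments(batch)
    take <- if (n > per_win) sort(sample.int(n, per_win)) else seq_len(n)
    sub <- batch$tensor[take, , , drop = FALSE]
    m <- detect_artifacts(structure(list(tensor = sub, fs = batch$fs,
                                         segment_times = batch$segment_times[take],
                                         overlap_mode = "overlapping"),
                                    class = "segment_batch"))
    sub <- sub[!m$flags, , , drop = FALSE]
    if (dim(sub)[1L] == 0L) next
    seg_list[[length(seg_list) + 1L]] <- sub
    lab <- c(lab, rep(lab_of(w), dim(sub)[1L]))
  }
  if (!length(seg_list)) stop("no artifact-free training segments")
  X <- abind_segments(seg_list)
  cw <- class_weights(lab)
  wts <- as.numeric(cw[as.character(lab)])
  # validation: contiguous artifact-free segments of validation windows
  val_X <- list(); val_lab <- c()
  for (w in windows_va) {
    batch <- .window_tensor(w, "contiguous")
    keep <- which(!w$mask)
    if (!length(keep)) next
    keep <- keep[seq(1L, length(keep), by = 4L)]    # thin for speed
    val_X[[length(val_X) + 1L]] <- batch$tensor[keep, , , drop = FALSE]
    val_lab <- c(val_lab, rep(lab_of(w), length(keep)))
  }
  Xv <- abind_segments(val_X)
  cwv <- class_weights(val_lab)
  wv <- as.numeric(cwv[as.character(val_lab)])

  params <- list(enc = encoder, head = head)
  opt <- rmsprop_init()
  skip <- if (frozen_blocks > 0L) {
    paste0("enc/blocks/b", seq_len(frozen_blocks), "/")
  } else character(0)
  step_fn <- function(params, idx) {
    fw <- encoder_fwd(params$enc, X[idx, , , drop = FALSE], train = TRUE,
                      frozen = frozen_blocks)
    params$enc <- fw$enc
    hg <- head_grad_feat(params$head, fw$emb, lab[idx], wts[idx])
    bw <- encoder_bwd(params$enc, fw$cache, hg$dfeat)
    list(params = params, grads = list(enc = bw$grads, head = hg$grads))
  }
  val_fn <- function(params) {
    emb <- encode_tensor(params$enc, Xv)
    z <- head_score(params$head, emb)
    if (task == "rass") {
      ordinal_nll(z, val_lab, head_thresholds(params$head), wv)$loss
    } else {
      .binary_nll(z, val_lab, wv)$loss
    }
  }
  res <- .stage_loop(step_fn, val_fn, params, opt, dim(X)[1L], config,
                     stage = 1L, skip = skip)
  list(encoder = res$params$enc, head = res$params$head,
       val_loss = res$val_loss, history = res$history,
       n_segments = dim(X)[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abind_segments <- function(mats) {
  mats <- mats[vapply(mats, function(m) length(dim(m)) == 3L, logical(1L))]
  tot <- sum(vapply(mats, function(m) dim(m)[1L], integer(1L)))
  out <- array(0, dim = c(tot, dim(mats[[1L]])[2L], dim(mats[[1L]])[3L]))
  at <- 1L
  for (m in mats) {
    n <- dim(m)[1L]
    out[at:(at + n - 1L), , ] <- m
    at <- at + n
  }
  out
}

# embeddings (900 x D) for each window, eval-mode encoder
.window_embeddings <- function(windows, encoder) {
  lapply(windows, function(w) {
    encode_tensor(encoder, .window_tensor(w, "contiguous")$tensor)
  })
}

# stage 2: first LSTM layer on 9.5-min subsequences of embeddings
.train_stage2 <- function(emb_tr, emb_va, lab_tr, lab_va, config, task) {
  seq_len_steps <- 142L
  step_steps <- max(1L, as.integer(round(config$seq_step_min * 15)))
  make_seqs <- function(embs, labs) {
    xs <- list(); ys <- c()
    for (i in seq_along(embs)) {
      E <- embs[[i]]
      starts <- seq(1L, nrow(E) - seq_len_steps + 1L, by = step_steps)
      for (s in starts) {
        xs[[length(xs) + 1L]] <- E[s:(s + seq_len_steps - 1L), , drop = FALSE]
        ys <- c(ys, labs[i])
      }
    }
    T_ <- seq_len_steps; D <- ncol(xs[[1L]])
    arr <- array(0, dim = c(length(xs), T_, D))
    for (i in seq_along(xs)) arr[i, , ] <- xs[[i]]
    list(x = arr, y = ys)
  }
  tr <- make_seqs(emb_tr, lab_tr)
  va <- make_seqs(emb_va, lab_va)
  cw <- class_weights(tr$y)
  wts <- as.numeric(cw[as.character(tr$y)])
  cwv <- class_weights(va$y)
  wv <- as.numeric(cwv[as.character(va$y)])
  D <- dim(tr$x)[3L]
  params <- list(lstm = nn_lstm_init(D, config$lstm_hidden),
                 head = make_head(config$lstm_hidden,
                                  if (task == "rass") "ordinal" else "binary"))
  opt <- rmsprop_init()
  step_fn <- function(params, idx) {
    fw <- nn_lstm_fwd(params$lstm, tr$x[idx, , , drop = FALSE])
    hg <- head_grad_seq(params$head, fw$out, tr$y[idx], wts[idx])
    bw <- nn_lstm_bwd(params$lstm, hg$dH, fw$cache)
    list(params = params, grads = list(lstm = bw$grads, head = hg$grads))
  }
  val_fn <- function(params) {
    fw <- nn_lstm_fwd(params$lstm, va$x)
    zbar <- .seq_mean_score(params$head, fw$out)
    if (task == "rass") {
      ordinal_nll(zbar, va$y, head_thresholds(params$head), wv)$loss
    } else .binary_nll(zbar, va$y, wv)$loss
  }
  res <- .stage_loop(step_fn, val_fn, params, opt, dim(tr$x)[1L], config,
                     stage = 2L)
  list(lstm = res$params$lstm, head = res$params$head,
       val_loss = res$val_loss, history = res$history)
}

.seq_mean_score <- function(head, H) {
  n <- dim(H)[1L]; T_ <- dim(H)[2L]
  flat <- matrix(H, nrow = n * T_)
  rowMeans(matrix(nn_dense_fwd(head$dense, flat)$out, n, T_))
}

# stage 3: second LSTM layer on full 1-h hidden sequences from layer 1
.train_stage3 <- function(h1_tr, h1_va, lab_tr, lab_va, config, task) {
  pack <- function(hs) {
    T_ <- nrow(hs[[1L]]); D <- ncol(hs[[1L]])
    arr <- array(0, dim = c(length(hs), T_, D))
    for (i in seq_along(hs)) arr[i, , ] <- hs[[i]]
    arr
  }
  xtr <- pack(h1_tr); xva <- pack(h1_va)
  cw <- class_weights(lab_tr)
  wts <- as.numeric(cw[as.character(lab_tr)])
  cwv <- class_weights(lab_va)
  wv <- as.numeric(cwv[as.character(lab_va)])
  params <- list(lstm = nn_lstm_init(dim(xtr)[3L], config$lstm_hidden),
                 head = make_head(config$lstm_hidden,
                                  if (task == "rass") "ordinal" else "binary"))
  opt <- rmsprop_init()
  step_fn <- function(params, idx) {
    fw <- nn_lstm_fwd(params$lstm, xtr[idx, , , drop = FALSE])
    hg <- head_grad_seq(params$head, fw$out, lab_tr[idx], wts[idx])
    bw <- nn_lstm_bwd(params$lstm, hg$dH, fw$cache)
    list(params = params, grads = list(lstm = bw$grads, head = hg$grads))
  }
  val_fn <- function(params) {
    fw <- nn_lstm_fwd(params$lstm, xva)
    zbar <- .seq_mean_score(params$head, fw$out)
    if (task == "rass") {
      ordinal_nll(zbar, lab_va, head_thresholds(params$head), wv)$loss
    } else .binary_nll(zbar, lab_va, wv)$loss
  }
  res <- .stage_loop(step_fn, val_fn, params, opt, dim(xtr)[1L], config,
                     stage = 3L)
  list(lstm = res$params$lstm, head = res$params$head,
       val_loss = res$val_loss, history = res$history)
}

#' Staged training of the CNN + LSTM tracker
#'
#' Stage 1 trains the convolutional encoder with a segment-level head
#' on artifact-free overlapping 4-s segments. Stage 2 freezes the CNN
#' and trains the first LSTM layer on 9.5-min sequences (142 contiguous
#' segments). Stage 3 freezes stages 1-2 and trains the second LSTM
#' layer on full 1-h sequences (900 segments). Each stage keeps the
#' parameters with minimum validation loss (early stopping). Windows
#' with more than 50% artifact segments are excluded up front; retained
#' windows keep all segments for sequence continuity. All randomness is
#' governed by `config$seed`.
#'
#' @param windows list from [cohort_windows()] (training patients only).
#' @param config a [model_config()].
#' @param task `"rass"` (ordinal) or `"cam"` (binary).
#' @param encoder optional pre-built encoder (used by the delirium
#'   transfer); `frozen_blocks` of it are kept fixed.
#' @param frozen_blocks number of leading CNN blocks excluded from
#'   stage-1 updates.
#' @return a `sedation_model`.
#' @export
train_staged <- function(windows, config = reduced_config(), task = "rass",
                         encoder = NULL, frozen_blocks = 0L) {
  task <- match.arg(task, c("rass", "cam"))
  # sequence retention rule, plus full 1-h coverage for fixed-length stages
  windows <- Filter(function(w) w$kept && ncol(w$signal) >= 900L * 250L,
                    windows)
  if (length(windows) < 4L) stop("not enough artifact-clean windows to train")
  .with_seed(config$seed, {
    lab_of <- function(w) if (task == "rass") w$rass else w$cam
    labs <- vapply(windows, lab_of, numeric(1L))
    # validation = 10% of assessments (at least 2), stratified by shuffle
    n <- length(windows)
    n_val <- max(2L, floor(config$val_frac * n))
    perm <- sample.int(n)
    va_idx <- perm[seq_len(n_val)]
    # ensure validation covers >= 2 classes when possible
    if (length(unique(labs[va_idx])) < 2L && length(unique(labs)) > 1L) {
      other <- perm[-seq_len(n_val)]
      swap <- other[which(labs[other] != labs[va_idx][1L])[1L]]
      va_idx <- c(va_idx[-1L], swap)
    }
    tr_idx <- setdiff(seq_len(n), va_idx)
    wtr <- windows[tr_idx]; wva <- windows[va_idx]

    if (is.null(encoder)) encoder <- make_encoder(config)
    head1 <- make_head(encoder$D, if (task == "rass") "ordinal" else "binary")
    s1 <- .train_stage1(wtr, wva, config, task, encoder, head1,
                        frozen_blocks = frozen_blocks)

    emb_tr <- .window_embeddings(wtr, s1$encoder)
    emb_va <- .window_embeddings(wva, s1$encoder)
    s2 <- .train_stage2(emb_tr, emb_va, vapply(wtr, lab_of, numeric(1L)),
                        vapply(wva, lab_of, numeric(1L)), config, task)

    h1_tr <- lapply(emb_tr, function(E) {
      nn_lstm_fwd(s2$lstm, array(E, dim = c(1L, nrow(E), ncol(E))))$out[1L, , ]
    })
    h1_va <- lapply(emb_va, function(E) {
      nn_lstm_fwd(s2$lstm, array(E, dim = c(1L, nrow(E), ncol(E))))$out[1L, , ]
    })
    s3 <- .train_stage3(h1_tr, h1_va, vapply(wtr, lab_of, numeric(1L)),
                        vapply(wva, lab_of, numeric(1L)), config, task)

    structure(list(config = config, task = task,
                   encoder = s1$encoder, head1 = s1$head,
                   lstm1 = s2$lstm, head2 = s2$head,
                   lstm2 = s3$lstm, head3 = s3$head,
                   val_losses = c(stage1 = s1$val_loss, stage2 = s2$val_loss,
                                  stage3 = s3$val_loss),
                   history = list(stage1 = s1$history, stage2 = s2$history,
                                  stage3 = s3$history),
                   seed = config$seed),
              class = "sedation_model")
  })
}

#' @export
print.sedation_model <- function(x, ...) {
  cat(sprintf("<sedation_model> task=%s, %d CNN blocks, LSTM hidden %d\n",
              x$task, x$config$n_blocks, x$config$lstm_hidden))
  cat("  stage validation losses:",
      paste(sprintf("%.3f", x$val_losses), collapse = ", "), "\n")
  invisible(x)
}

#' Learned z-score thresholds of a RASS model
#' @param model a `sedation_model` with `task = "rass"`.
#' @return numeric vector of 5 strictly increasing thresholds.
#' @export
model_thresholds <- function(model) {
  stopifnot(model$task == "rass")
  head_thresholds(model$head3)
}

#' Transfer a RASS model to the delirium (CAM-ICU) task
#'
#' Copies the trained RASS convolutional encoder, freezes its first `M`
#' blocks, and retrains the remaining blocks plus fresh recurrent
#' layers and a binary head on delirium labels (windows at RASS -4/-5
#' counted positive) with inverse-frequency class weights.
#'
#' @param rass_model a trained `sedation_model` (task "rass").
#' @param windows training windows from [cohort_windows()].
#' @param M number of leading CNN blocks to freeze (default from config).
#' @param config optional config override.
#' @return a `sedation_model` with `task = "cam"`.
#' @export
transfer_to_cam <- function(rass_model, windows, M = NULL, config = NULL) {
  stopifnot(inherits(rass_model, "sedation_model"),
            rass_model$task == "rass")
  config <- config %||% rass_model$config
  M <- M %||% config$transfer_M
  if (M < 1L || M > config$n_blocks) stop("M out of 1..n_blocks")
  model <- train_staged(windows, config, task = "cam",
                        encoder = rass_model$encoder, frozen_blocks = M)
  model$transfer_M <- M
  model
}

## ---- prediction -------------------------------------------------------

# per-step z (or delirium probability) for a contiguous segment tensor
.model_step_scores <- function(model, X) {
  emb <- encode_tensor(model$encoder, X)
  h1 <- nn_lstm_fwd(model$lstm1,
                    array(emb, dim = c(1L, nrow(emb), ncol(emb))))$out
  h2 <- nn_lstm_fwd(model$lstm2, h1)$out[1L, , , drop = FALSE]
  z <- head_score(model$head3, matrix(h2[1L, , ], dim(h2)[2L]))
  if (model$task == "cam") .sigmoid(z) else z
}

#' Predict the sedation level / delirium probability of one window
#'
#' Scores every contiguous 4-s segment through CNN -> LSTM1 -> LSTM2,
#' averages the per-step z-score (RASS) or probability (CAM-ICU) across
#' the window, and for RASS discretizes the average with the learned
#' thresholds.
#'
#' @param model a `sedation_model`.
#' @param window an `eeg_record` at 62.5 Hz, a `segment_batch`
#'   (contiguous), or an N x 2 x 250 array.
#' @return for RASS: list(z_trace, z, level, thresholds); for CAM:
#'   list(p_trace, p).
#' @export
predict_window <- function(model, window) {
  X <- if (inherits(window, "eeg_record")) {
    segment(window, "contiguous")$tensor
  } else if (inherits(window, "segment_batch")) {
    window$tensor
  } else window
  if (dim(X)[1L] == 0L) stop("empty window")
  s <- .model_step_scores(model, X)
  if (model$task == "rass") {
    list(z_trace = s, z = mean(s),
         level = discretize(mean(s), model_thresholds(model)),
         thresholds = model_thresholds(model))
  } else {
    list(p_trace = s, p = mean(s))
  }
}

#' Continuous tracking trace over a long recording
#'
#' Emits an updated prediction every 4 s: the recurrent state carries
#' the trailing context, and at each step the reported level is the
#' discretized mean z over the trailing window (up to 1 h).
#'
#' @param model a `sedation_model`.
#' @param rec an `eeg_record` at 62.5 Hz (bipolar pair).
#' @param context_steps trailing steps averaged for the reported value
#'   (default 900 = 1 h).
#' @return data.frame: time_s, z (or p_delirium), and for RASS
#'   rass_pred.
#' @export
track_trace <- function(model, rec, context_steps = 900L) {
  batch <- segment(rec, "contiguous")
  s <- .model_step_scores(model, batch$tensor)
  n <- length(s)
  csum <- cumsum(s)
  lo <- pmax(0L, seq_len(n) - context_steps)
  trail <- (csum - c(0, csum)[lo + 1L]) / (seq_len(n) - lo)
  if (model$task == "rass") {
    data.frame(time_s = batch$segment_times + 4,
               z = trail,
               rass_pred = discretize(trail, model_thresholds(model)))
  } else {
    data.frame(time_s = batch$segment_times + 4, p_delirium = trail)
  }
}
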