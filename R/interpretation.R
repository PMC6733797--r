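#' Gradient of a model's final z-score with respect to its input
#'
#' Generic: implemented for trained `sedation_model`s (exact backward
#' pass through LSTM2, LSTM1 and the convolutional encoder) and for
#' `linear_surrogate` scorers (whose gradient is the weight vector).
#'
#' @param model scoring model.
#' @param X input window: S x 2 x 250 array of contiguous segments.
#' @param ... method-specific arguments.
#' @return array of the same shape as `X`.
#' @export
input_gradient <- function(model, X, ...) UseMethod("input_gradient")

#' @param at `"final"` (gradient of the last step's z, as used for
#'   interpretation) or `"mean"` (gradient of the across-step mean z).
#' @rdname input_gradient
#' @export
input_gradient.sedation_model <- function(model, X, at = c("final", "mean"),
                                          ...) {
  at <- match.arg(at)
  if (inherits(X, "segment_batch")) X <- X$tensor
  S <- dim(X)[1L]
  fw <- encoder_fwd(model$encoder, X, train = FALSE)
  E <- array(fw$emb, dim = c(1L, S, ncol(fw$emb)))
  l1 <- nn_lstm_fwd(model$lstm1, E)
  l2 <- nn_lstm_fwd(model$lstm2, l1$out)
  H2 <- dim(l2$out)[3L]
  # d z / d h2 at the selected step(s): the head's dense weights
  w <- as.numeric(model$head3$dense$W)
  dH2 <- array(0, dim = c(1L, S, H2))
  if (at == "final") {
    dH2[1L, S, ] <- w
  } else {
    for (t in seq_len(S)) dH2[1L, t, ] <- w / S
  }
  b2 <- nn_lstm_bwd(model$lstm2, dH2, l2$cache)
  b1 <- nn_lstm_bwd(model$lstm1, b2$dX, l1$cache)
  dE <- matrix(b1$dX[1L, , ], S)
  eb <- encoder_bwd(model$encoder, fw$cache, dE)
  eb$dX
}

#' Linear surrogate scorer
#'
#' A fixed linear functional `z = sum(w * x)` over a window, used to
#' validate the saliency machinery: its input gradient is exactly `w`.
#'
#' @param w numeric array of weights (same shape as the windows it
#'   scores).
#' @return object of class `linear_surrogate`.
#' @export
linear_surrogate <- function(w) {
  structure(list(w = w), class = "linear_surrogate")
}

#' @rdname input_gradient
#' @export
input_gradient.linear_surrogate <- function(model, X, ...) {
  g <- array(model$w, dim = dim(X))
  g
}

#' Gradient saliency map with percentile highlighting
#'
#' Computes the gradient of the window-final z-score with respect to
#' every input sample and marks the samples whose absolute gradient
#' exceeds the 95th percentile within the window (pooled over both
#' channels): the parts of the signal with the largest influence on
#' the prediction.
#'
#' @param model a `sedation_model` or `linear_surrogate`.
#' @param window S x 2 x 250 array (or `segment_batch`) of contiguous
#'   segments.
#' @param percentile highlighting percentile (default 0.95).
#' @param at see [input_gradient()].
#' @return list of class `saliency_map`: `gradients` (2 x S*250 matrix,
#'   channels x samples), `highlight` (logical, same shape),
#'   `threshold`, `fs`.
#' @export
saliency <- function(model, window, percentile = 0.95, at = "final") {
  X <- if (inherits(window, "segment_batch")) window$tensor else window
  g <- input_gradient(model, X, at = at)
  if (any(!is.finite(g))) stop("non-finite gradients")
  S <- dim(g)[1L]; C <- dim(g)[2L]; T_ <- dim(g)[3L]
  flat <- matrix(0, nrow = C, ncol = S * T_)
  for (s in seq_len(S)) {
    flat[, ((s - 1L) * T_ + 1L):(s * T_)] <- g[s, , ]
  }
  thr <- stats::quantile(abs(flat), percentile, names = FALSE)
  structure(list(gradients = flat, highlight = abs(flat) > thr,
                 threshold = thr, fs = 62.5),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d, %.2f%% highlighted (thr %.3g)\n",
              nrow(x$gradients), ncol(x$gradients),
              100 * mean(x$highlight), x$threshold))
  invisible(x)
}
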