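#' Artifact rule parameters
#'
#' Thresholds for the four segment-level artifact rules, evaluated per
#' channel on 4-s segments at 62.5 Hz:
#' 1. maximum absolute amplitude above `max_amp` (1000 uV);
#' 2. sample standard deviation below `min_std` (0.2 uV);
#' 3. an absolute change of more than `max_jump` (900 uV) within any
#'    `jump_window` (0.1 s) span;
#' 4. a staircase-like step in the log power spectrum: the maximum of
#'    the convolution of a zero-sum step kernel with the 10*log10
#'    spectrum exceeds `staircase_threshold` (10), flagging
#'    nonphysiologic single-frequency machine artifacts.
#'
#' The staircase kernel defaults to `half_width` bins at -1/half_width
#' followed by `half_width` bins at +1/half_width, so its response is
#' the dB step height between adjacent spectral neighborhoods. The
#' spectrum is a Welch estimate on 2-s Hann subwindows (50% overlap,
#' 0.5 Hz resolution) over 0.5-20 Hz; averaging keeps the log-spectrum
#' fluctuation of broadband noise well below the threshold.
#'
#' @param max_amp amplitude ceiling, uV.
#' @param min_std flatline floor, uV.
#' @param max_jump fast-change ceiling, uV.
#' @param jump_window span for rule 3, seconds.
#' @param staircase_threshold dB step threshold for rule 4.
#' @param staircase_kernel zero-sum numeric kernel on log-spectrum bins;
#'   `NULL` builds the default difference-of-steps kernel.
#' @param kernel_half_width bins per kernel lobe for the default kernel.
#' @return list of class `artifact_params`.
#' @export
artifact_params <- function(max_amp = 1000, min_std = 0.2, max_jump = 900,
                            jump_window = 0.1, staircase_threshold = 10,
                            staircase_kernel = NULL, kernel_half_width = 4L) {
  if (is.null(staircase_kernel)) {
    h <- kernel_half_width
    staircase_kernel <- c(rep(-1 / h, h), rep(1 / h, h))
  }
  if (abs(sum(staircase_kernel)) > 1e-9) {
    stop("staircase kernel must sum to zero")
  }
  stopifnot(max_amp > 0, min_std > 0, max_jump > 0, jump_window > 0,
            staircase_threshold > 0)
  structure(list(max_amp = max_amp, min_std = min_std, max_jump = max_jump,
                 jump_window = jump_window,
                 staircase_threshold = staircase_threshold,
                 staircase_kernel = staircase_kernel),
            class = "artifact_params")
}

# Batched Welch log-spectrum: X is T x N (segments in columns).
# Returns 10*log10 power (bins x N) over 0.5-20 Hz.
.welch_db_mat <- function(X, fs, win_sec = 2) {
  T_samp <- nrow(X)
  L <- as.integer(round(win_sec * fs))
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, T_samp - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  nb <- L %/% 2L + 1L
  acc <- matrix(0, nrow = nb, ncol = ncol(X))
  for (s in starts) {
    Y <- X[s:(s + L - 1L), , drop = FALSE] * w
    P <- abs(stats::mvfft(Y))^2
    acc <- acc + P[seq_len(nb), , drop = FALSE]
  }
  pw <- acc / (length(starts) * sum(w^2))
  freq <- (seq_len(nb) - 1L) * fs / L
  keep <- freq >= 0.5 & freq <= 20
  10 * log10(pmax(pw[keep, , drop = FALSE], 1e-20))
}

# max over positions of the kernel sliding along each column of db
.staircase_response_mat <- function(db, kernel) {
  k <- length(kernel)
  nb <- nrow(db)
  if (nb < k) return(rep(-Inf, ncol(db)))
  n_pos <- nb - k + 1L
  resp <- matrix(-Inf, nrow = n_pos, ncol = ncol(db))
  for (j in seq_len(n_pos)) {
    resp[j, ] <- crossprod(kernel, db[j:(j + k - 1L), , drop = FALSE])
  }
  apply(resp, 2L, max)
}

#' Detect artifacts in 4-s segments
#'
#' Applies the four artifact rules per channel; a segment is flagged
#' when any rule fires in any channel. Evaluation is batched across
#' segments so hour-long windows are screened quickly.
#'
#' @param batch a `segment_batch` at 62.5 Hz.
#' @param params an [artifact_params()] list.
#' @return an `artifact_mask`: list with `flags` (N logical) and
#'   `per_rule` (N x 4 logical matrix).
#' @export
detect_artifacts <- function(batch, params = artifact_params()) {
  stopifnot(inherits(batch, "segment_batch"))
  N <- n_segments(batch)
  if (N == 0L) stop("empty segment batch")
  C <- dim(batch$tensor)[2L]
  fs <- batch$fs
  T_samp <- dim(batch$tensor)[3L]
  lag_max <- max(1L, as.integer(round(params$jump_window * fs)))
  per_rule <- matrix(FALSE, nrow = N, ncol = 4L,
                     dimnames = list(NULL, c("amplitude", "flatline",
                                             "fast_change", "staircase")))
  for (c in seq_len(C)) {
    X <- t(matrix(batch$tensor[, c, ], nrow = N))     # T x N
    per_rule[, 1L] <- per_rule[, 1L] |
      (colSums(abs(X) > params$max_amp) > 0L)
    mu <- colMeans(X)
    v <- (colSums(X^2) - T_samp * mu^2) / (T_samp - 1L)
    per_rule[, 2L] <- per_rule[, 2L] | (sqrt(pmax(v, 0)) < params$min_std)
    r3 <- rep(FALSE, N)
    for (k in seq_len(lag_max)) {
      D <- X[(k + 1L):T_samp, , drop = FALSE] - X[seq_len(T_samp - k), ,
                                                  drop = FALSE]
      r3 <- r3 | (colSums(abs(D) > params$max_jump) > 0L)
    }
    per_rule[, 3L] <- per_rule[, 3L] | r3
    db <- .welch_db_mat(X, fs)
    per_rule[, 4L] <- per_rule[, 4L] |
      (.staircase_response_mat(db, params$staircase_kernel) >
         params$staircase_threshold)
  }
  structure(list(flags = apply(per_rule, 1L, any), per_rule = per_rule),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d/%d segments flagged\n",
              sum(x$flags), length(x$flags)))
  print(colSums(x$per_rule))
  invisible(x)
}

#' Sequence-level retention rule
#'
#' A sequence (e.g. a 1-h window of contiguous segments) is dropped when
#' strictly more than half of its segments are artifact. Retained
#' sequences keep all segments, artifacts included, to preserve temporal
#' continuity for the recurrent layers.
#'
#' @param masks a list of `artifact_mask` objects, one per sequence, or a
#'   single mask.
#' @param max_fraction drop threshold (default 0.5, exclusive).
#' @return logical vector, `TRUE` = keep.
#' @export
filter_sequences <- function(masks, max_fraction = 0.5) {
  if (inherits(masks, "artifact_mask")) masks <- list(masks)
  vapply(masks, function(m) {
    if (!length(m$flags)) stop("sequence with no segments")
    mean(m$flags) <= max_fraction
  }, logical(1L))
}
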