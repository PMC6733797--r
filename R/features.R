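#' Welch power spectral density
#'
#' Hann-windowed Welch estimate with 50% overlap, scaled so that the sum
#' of `psd * df` over all bins equals the mean-square power of the
#' signal (one-sided spectrum).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param win_sec subwindow length in seconds (default 1).
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, win_sec = 1) {
  n <- length(x)
  L <- min(n, as.integer(round(win_sec * fs)))
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  nb <- L %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    acc <- acc + abs(stats::fft(seg)[seq_len(nb)])^2
  }
  # one-sided density: double interior bins; Parseval-consistent scaling
  df <- fs / L
  dens <- acc / (length(starts) * sum(w^2) * fs)
  dens[-1L] <- 2 * dens[-1L]
  if (L %% 2L == 0L) dens[nb] <- dens[nb] / 2
  list(freq = (seq_len(nb) - 1L) * df, psd = dens)
}

.band_edges <- list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12))

#' Spectral band powers of one 4-s segment
#'
#' Absolute delta (0-4 Hz), theta (4-8 Hz) and alpha (8-12 Hz) band
#' powers from a Welch estimate (1-s subwindows, 50% overlap), averaged
#' across channels, plus relative powers normalized by the total 0-12 Hz
#' power.
#'
#' @param seg numeric matrix channels x samples (or a vector).
#' @param fs sampling rate, Hz (62.5 for pipeline segments).
#' @param win_sec Welch subwindow length, seconds (longer windows give
#'   finer frequency resolution on long inputs).
#' @return named list: `delta`, `theta`, `alpha` (uV^2), `rdelta`,
#'   `rtheta`, `ralpha` (unitless; `NA` when total power is 0).
#' @export
band_powers <- function(seg, fs = 62.5, win_sec = 1) {
  if (is.vector(seg)) seg <- matrix(seg, nrow = 1L)
  abs_p <- c(delta = 0, theta = 0, alpha = 0)
  for (c in seq_len(nrow(seg))) {
    sp <- welch_psd(seg[c, ], fs, win_sec = win_sec)
    df <- sp$freq[2L] - sp$freq[1L]
    for (b in names(.band_edges)) {
      e <- .band_edges[[b]]
      sel <- sp$freq >= e[1L] & sp$freq < e[2L]
      abs_p[b] <- abs_p[b] + sum(sp$psd[sel]) * df
    }
  }
  abs_p <- abs_p / nrow(seg)
  total <- sum(abs_p)
  rel <- if (total > 0) abs_p / total else c(NA_real_, NA_real_, NA_real_)
  list(delta = abs_p[["delta"]], theta = abs_p[["theta"]],
       alpha = abs_p[["alpha"]],
       rdelta = rel[[1L]], rtheta = rel[[2L]], ralpha = rel[[3L]])
}

#' Analytic-signal amplitude envelope
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT),
#' optionally smoothed with a centered running median. The raw
#' analytic magnitude ripples at the troughs of low-frequency waves;
#' the median removes that ripple while preserving the sharp edges of
#' burst/suppression alternation (a moving mean would smear them).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param smooth_sec running-median length in seconds (0 = none).
#' @return numeric vector of envelope values (uV).
#' @export
signal_envelope <- function(x, fs, smooth_sec = 0.5) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth_sec > 0) {
    k <- max(1L, as.integer(round(smooth_sec * fs)))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L && n > k) env <- as.numeric(stats::runmed(env, k))
  }
  env
}

#' Burst suppression ratio
#'
#' Fraction of time the signal envelope lies below a threshold
#' (default 5 uV): the proportion of suppressed EEG within the window.
#' The sub-threshold indicator is computed per channel and averaged
#' across channels before time-averaging.
#'
#' @param window an `eeg_record` (any duration > 0).
#' @param envelope_threshold suppression threshold, uV.
#' @param smooth_sec envelope smoothing, seconds.
#' @return fraction in \[0, 1\].
#' @export
burst_suppression_ratio <- function(window, envelope_threshold = 5,
                                    smooth_sec = 0.5) {
  stopifnot(inherits(window, "eeg_record"), ncol(window$data) > 0L)
  ind <- vapply(seq_len(nrow(window$data)), function(c) {
    env <- signal_envelope(window$data[c, ], window$fs, smooth_sec)
    as.numeric(env < envelope_threshold)
  }, numeric(ncol(window$data)))
  mean(rowMeans(as.matrix(ind)))
}

#' Baseline feature vector for a 1-h window
#'
#' The non-deep baseline input: per-segment band powers averaged across
#' the window's artifact-free contiguous 4-s segments, plus the burst
#' suppression ratio of the whole window.
#'
#' @param window an `eeg_record` at 62.5 Hz (preprocessed bipolar pair).
#' @param mask optional `artifact_mask` for the window's contiguous
#'   segments; flagged segments are excluded from the spectral averages.
#' @param envelope_threshold BSR threshold, uV.
#' @return named list with `delta`, `theta`, `alpha`, `rdelta`,
#'   `rtheta`, `ralpha` (window means) and `bsr`.
#' @export
baseline_features <- function(window, mask = NULL, envelope_threshold = 5) {
  batch <- segment(window, mode = "contiguous")
  keep <- rep(TRUE, n_segments(batch))
  if (!is.null(mask)) {
    stopifnot(length(mask$flags) == n_segments(batch))
    keep <- !mask$flags
  }
  if (!any(keep)) stop("all segments in the window are artifact")
  feats <- lapply(which(keep), function(i) {
    band_powers(matrix(batch$tensor[i, , ], nrow = dim(batch$tensor)[2L]),
                fs = batch$fs)
  })
  agg <- lapply(names(feats[[1L]]), function(nm) {
    mean(vapply(feats, function(f) f[[nm]], numeric(1L)), na.rm = TRUE)
  })
  names(agg) <- names(feats[[1L]])
  agg$bsr <- burst_suppression_ratio(window, envelope_threshold)
  agg
}
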