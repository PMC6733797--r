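#' Default preprocessing filter parameters
#'
#' Zero-phase (forward-backward) IIR filtering: a Butterworth band-stop
#' notch around the mains frequency, a high-pass at 0.5 Hz and a
#' low-pass at 20 Hz, followed by downsampling to 62.5 Hz. The
#' high-pass and low-pass are applied as separate sections rather than
#' one high-order bandpass for numerical stability at the very low
#' normalized edge frequency.
#'
#' @param notch_hz mains frequency to suppress (Hz).
#' @param notch_bw full width of the band-stop (Hz).
#' @param hp_hz high-pass cutoff (Hz).
#' @param lp_hz low-pass cutoff (Hz).
#' @param hp_order,lp_order,notch_order Butterworth orders (per pass).
#' @param target_fs output sampling rate (Hz).
#' @return list of filter parameters.
#' @export
filter_params <- function(notch_hz = 60, notch_bw = 4, hp_hz = 0.5,
                          lp_hz = 20, hp_order = 2L, lp_order = 4L,
                          notch_order = 2L, target_fs = 62.5) {
  list(notch_hz = notch_hz, notch_bw = notch_bw, hp_hz = hp_hz,
       lp_hz = lp_hz, hp_order = hp_order, lp_order = lp_order,
       notch_order = notch_order, target_fs = target_fs)
}

.filtfilt_mat <- function(flt, x) {
  t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
}

#' Filter and downsample a recording
#'
#' Notch filter at the mains frequency, band-limit to 0.5-20 Hz and
#' downsample to 62.5 Hz. All filters are applied forward-backward
#' (zero phase), which preserves waveform morphology for later
#' gradient-saliency inspection. The 20 Hz low-pass also serves as the
#' anti-alias filter for the 4x decimation (post-decimation Nyquist
#' 31.25 Hz).
#'
#' @param rec an `eeg_record` with `fs >= 125` Hz.
#' @param params see [filter_params()].
#' @return an `eeg_record` at `params$target_fs` Hz.
#' @export
filter_and_resample <- function(rec, params = filter_params()) {
  stopifnot(inherits(rec, "eeg_record"))
  fs <- rec$fs
  if (fs < 125) stop("sampling rate must be at least 125 Hz for the 0.5-20 Hz passband")
  nyq <- fs / 2
  x <- rec$data

  if (params$notch_hz + params$notch_bw / 2 < 0.95 * nyq) {
    w <- c(params$notch_hz - params$notch_bw / 2,
           params$notch_hz + params$notch_bw / 2) / nyq
    x <- .filtfilt_mat(signal::butter(params$notch_order, w, type = "stop"), x)
  }
  x <- .filtfilt_mat(signal::butter(params$hp_order, params$hp_hz / nyq,
                                    type = "high"), x)
  x <- .filtfilt_mat(signal::butter(params$lp_order, params$lp_hz / nyq,
                                    type = "low"), x)

  ratio <- fs / params$target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, ncol(x), by = as.integer(round(ratio)))
    x <- x[, idx, drop = FALSE]
  } else {
    # rational resampling for non-integer ratios
    frac <- .rat_approx(params$target_fs / fs)
    x <- t(apply(x, 1L, function(ch) signal::resample(ch, frac[1L], frac[2L])))
  }
  eeg_record(x, params$target_fs, rec$channel_labels, rec$start_time)
}

.rat_approx <- function(x, max_den = 10000L) {
  # continued-fraction rational approximation of x = p/q
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Extract the 1-h analysis window around an assessment
#'
#' Returns up to 30 min of signal before and after the assessment time.
#' Recorded assessment times can be imprecise, so the full hour is kept
#' to make sure the true assessment moment is covered. Windows truncated
#' by the recording edges are returned with a coverage attribute and a
#' warning rather than rejected.
#'
#' @param rec an `eeg_record`.
#' @param at assessment time in seconds (same origin as `rec$start_time`),
#'   or a 1-row `assessment_table`.
#' @param half_width half window width in seconds (default 1800).
#' @return an `eeg_record` covering the overlap of
#'   `[at - half_width, at + half_width]` with the recording; attribute
#'   `coverage` holds the achieved duration in seconds.
#' @export
extract_window <- function(rec, at, half_width = 1800) {
  stopifnot(inherits(rec, "eeg_record"))
  if (inherits(at, "data.frame")) at <- at$time[1L]
  t0 <- rec$start_time
  t1 <- t0 + record_duration(rec)
  lo <- max(at - half_width, t0)
  hi <- min(at + half_width, t1)
  if (hi <= lo) stop("assessment window has no overlap with the recording")
  i0 <- floor((lo - t0) * rec$fs) + 1L
  i1 <- min(ncol(rec$data), i0 + as.integer(round((hi - lo) * rec$fs)) - 1L)
  out <- eeg_record(rec$data[, i0:i1, drop = FALSE], rec$fs,
                    rec$channel_labels, start_time = t0 + (i0 - 1L) / rec$fs)
  cov <- (i1 - i0 + 1L) / rec$fs
  attr(out, "coverage") <- cov
  if (cov < 2 * half_width - 1 / rec$fs) {
    warning(sprintf("window truncated at recording edge: %.0f of %.0f s", cov,
                    2 * half_width))
  }
  out
}

#' Epoch a recording into 4-s segments
#'
#' Overlapping mode (2-s step) is used to augment training of the
#' segment encoder; contiguous mode (4-s step) is used for all sequence
#' modeling and inference, so that a 9.5-min sequence holds 142
#' segments and a 1-h sequence holds 900.
#'
#' @param rec an `eeg_record` at 62.5 Hz.
#' @param mode `"contiguous"` (4-s step) or `"overlapping"` (2-s step).
#' @param seg_len segment length in seconds (default 4).
#' @return a `segment_batch`: list with `tensor` (N x C x T array, uV),
#'   `fs`, `segment_times` (start time of each segment, s), `overlap_mode`.
#' @export
segment <- function(rec, mode = c("contiguous", "overlapping"), seg_len = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "eeg_record"))
  fs <- rec$fs
  T_samp <- as.integer(round(seg_len * fs))
  n_total <- ncol(rec$data)
  if (n_total < T_samp) stop("recording shorter than one segment")
  step <- if (mode == "contiguous") T_samp else as.integer(round(T_samp / 2))
  starts <- seq(1L, n_total - T_samp + 1L, by = step)
  C <- nrow(rec$data)
  tensor <- array(0, dim = c(length(starts), C, T_samp))
  for (i in seq_along(starts)) {
    tensor[i, , ] <- rec$data[, starts[i]:(starts[i] + T_samp - 1L)]
  }
  structure(
    list(tensor = tensor, fs = fs,
         segment_times = rec$start_time + (starts - 1L) / fs,
         overlap_mode = mode),
    class = "segment_batch"
  )
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<segment_batch> %d segments x %d ch x %d samples @ %g Hz (%s)\n",
              d[1L], d[2L], d[3L], x$fs, x$overlap_mode))
  invisible(x)
}

#' Number of segments in a batch
#' @param batch a `segment_batch`.
#' @export
n_segments <- function(batch) dim(batch$tensor)[1L]

#' Persist / load an epoched segment batch
#'
#' Segments plus their times, sampling rate and (optionally) the filter
#' provenance are stored in a single serialized container.
#'
#' @param batch a `segment_batch`.
#' @param path output path.
#' @param provenance optional list recorded alongside (e.g. filter params).
#' @rdname segment-io
#' @export
save_segments <- function(batch, path, provenance = NULL) {
  stopifnot(inherits(batch, "segment_batch"))
  saveRDS(list(batch = batch, provenance = provenance), path)
  invisible(path)
}

#' @rdname segment-io
#' @export
load_segments <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !inherits(obj$batch, "segment_batch")) {
    stop("file does not hold a segment batch")
  }
  obj$batch
}

#' End-to-end preprocessing of one assessment window
#'
#' Re-references to the bipolar frontal montage if needed, extracts the
#' 1-h window around the assessment, filters and downsamples, and
#' epochs into 4-s segments.
#'
#' @inheritParams extract_window
#' @inheritParams segment
#' @param params filter parameters, see [filter_params()].
#' @return a `segment_batch`.
#' @export
preprocess_window <- function(rec, at, mode = "contiguous",
                              params = filter_params(), half_width = 1800) {
  rec <- rereference(rec)
  win <- suppressWarnings(extract_window(rec, at, half_width = half_width))
  win <- filter_and_resample(win, params)
  segment(win, mode = mode)
}
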