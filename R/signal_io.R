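#' Construct an EEG recording object
#'
#' Container for a continuous multichannel EEG signal. Data are stored in
#' microvolts as a channels x samples matrix together with the sampling
#' rate, ordered channel labels and a start time.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names, one per row.
#' @param start_time recording start in seconds (absolute or relative origin).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_labels, start_time = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("need one channel label per data row")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         start_time = as.numeric(start_time)),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_record`.
#' @return numeric scalar, seconds.
#' @export
record_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct a behavioral assessment table
#'
#' Timestamped behavioral labels: RASS (ordinal, -5..0 only: normal or
#' decreased arousal) or CAM-ICU (binary delirium screen).
#'
#' @param time numeric, assessment times in seconds.
#' @param kind character, each one of `"RASS"` or `"CAM-ICU"`.
#' @param value integer labels; RASS in -5..0, CAM-ICU in 0/1.
#' @param rater character, each one of `"nurse"`, `"technician"`, `"synthetic"`.
#' @param patient optional patient identifier (recycled).
#' @return data.frame with class `assessment_table`.
#' @export
assessments <- function(time, kind, value, rater = "synthetic", patient = NA) {
  n <- length(time)
  if (n > 0L) kind <- match.arg(kind, c("RASS", "CAM-ICU"), several.ok = TRUE)
  else kind <- character(0)
  df <- data.frame(
    time = as.numeric(time),
    kind = rep_len(kind, n),
    value = as.integer(value),
    rater = rep_len(as.character(rater), n),
    patient = rep_len(patient, n),
    stringsAsFactors = FALSE
  )
  bad_rass <- df$kind == "RASS" & (df$value < -5L | df$value > 0L)
  if (any(bad_rass)) stop("RASS values must lie in -5..0")
  bad_cam <- df$kind == "CAM-ICU" & !(df$value %in% c(0L, 1L))
  if (any(bad_cam)) stop("CAM-ICU values must be 0 or 1")
  ok_rater <- df$rater %in% c("nurse", "technician", "synthetic")
  if (!all(ok_rater)) stop("rater must be nurse, technician or synthetic")
  class(df) <- c("assessment_table", "data.frame")
  df
}

#' Read / write assessment tables
#'
#' Flat CSV with columns time_s, kind, value, rater and optionally patient.
#'
#' @param path file path.
#' @rdname assessment-io
#' @return `read_assessments()` returns an `assessment_table`.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "kind", "value", "rater")
  if (!all(need %in% names(df))) {
    stop("assessment CSV must have columns ", paste(need, collapse = ", "))
  }
  assessments(df$time_s, df$kind, df$value, df$rater,
              patient = if ("patient" %in% names(df)) df$patient else NA)
}

#' @param x an `assessment_table`.
#' @rdname assessment-io
#' @export
write_assessments <- function(x, path) {
  out <- data.frame(time_s = x$time, kind = x$kind, value = x$value,
                    rater = x$rater)
  if (!all(is.na(x$patient))) out$patient <- x$patient
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# fixed-width ASCII field helpers for the EDF header
.edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

.edf_read_field <- function(con, width, n = 1L) {
  raw <- readChar(con, nchars = width * n, useBytes = TRUE)
  starts <- seq(1L, by = width, length.out = n)
  trimws(substring(raw, starts, starts + width - 1L))
}

#' Write an EEG recording to an EDF file
#'
#' Plain EDF (16-bit integer samples with per-signal physical scaling).
#' The record duration is 1 s, so `fs` must be a positive integer
#' number of samples per second for EDF output.
#'
#' @param rec an `eeg_record` (data in microvolts).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate (1-s records)")
  }
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")
  dat <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  phys_min <- pmin(apply(dat, 1L, min), -1)
  phys_max <- pmax(apply(dat, 1L, max), 1)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad("X X X X", 80L),
    .edf_pad("Startdate X X X X", 80L),
    .edf_pad("01.01.00", 8L),
    .edf_pad("00.00.00", 8L),
    .edf_pad(256L * (1L + ns), 8L),
    .edf_pad("", 44L),
    .edf_pad(n_rec, 8L),
    .edf_pad("1", 8L),
    .edf_pad(ns, 4L)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  field <- function(vals, w) {
    writeChar(paste0(vapply(vals, .edf_pad, "", width = w), collapse = ""),
              con, eos = NULL, useBytes = TRUE)
  }
  field(rec$channel_labels, 16L)
  field(rep("", ns), 80L)                      # transducer
  field(rep("uV", ns), 8L)                     # physical dimension
  field(sprintf("%.6g", phys_min), 8L)
  field(sprintf("%.6g", phys_max), 8L)
  field(rep(dig_min, ns), 8L)
  field(rep(dig_max, ns), 8L)
  field(rep("", ns), 80L)                      # prefiltering
  field(rep(fs, ns), 8L)
  field(rep("", ns), 32L)

  # digital conversion per channel, then interleave records
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- matrix(0L, nrow = ns, ncol = ncol(dat))
  for (i in seq_len(ns)) {
    d <- round((dat[i, ] - phys_min[i]) / scale[i]) + dig_min
    dig[i, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an `eeg_record`
#'
#' Supports plain EDF/EDF+ with a common sampling rate across EEG signals;
#' annotation channels are skipped. Physical units are assumed to be
#' microvolts (or convertible by the stated scaling).
#'
#' @param path EDF file path.
#' @return an `eeg_record`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  .edf_read_field(con, 8L)                      # version
  .edf_read_field(con, 80L); .edf_read_field(con, 80L)
  .edf_read_field(con, 8L); .edf_read_field(con, 8L)
  .edf_read_field(con, 8L)                      # header bytes
  .edf_read_field(con, 44L)
  n_rec <- as.integer(.edf_read_field(con, 8L))
  rec_dur <- as.numeric(.edf_read_field(con, 8L))
  ns <- as.integer(.edf_read_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF file contains no signals")

  labels <- .edf_read_field(con, 16L, ns)
  .edf_read_field(con, 80L, ns)
  .edf_read_field(con, 8L, ns)
  phys_min <- as.numeric(.edf_read_field(con, 8L, ns))
  phys_max <- as.numeric(.edf_read_field(con, 8L, ns))
  dig_min <- as.numeric(.edf_read_field(con, 8L, ns))
  dig_max <- as.numeric(.edf_read_field(con, 8L, ns))
  .edf_read_field(con, 80L, ns)
  spr <- as.integer(.edf_read_field(con, 8L, ns))
  .edf_read_field(con, 32L, ns)

  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop("EDF file has no EEG channels")
  if (length(unique(spr[keep])) != 1L) {
    stop("mixed sampling rates across EEG signals are not supported")
  }
  fs <- spr[keep][1L] / rec_dur
  out <- matrix(NA_real_, nrow = sum(keep), ncol = n_rec * spr[keep][1L])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  row_of <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L,
                     endian = "little", signed = TRUE)
      if (keep[s]) {
        idx <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        out[row_of[s], idx] <- phys_min[s] + (raw - dig_min[s]) * scale[s]
      }
    }
  }
  eeg_record(out, fs = fs, channel_labels = labels[keep])
}

#' Load an EEG recording from disk
#'
#' @param path file path.
#' @param format `"edf"` or `"rds"` (serialized `eeg_record`); guessed from
#'   the file extension by default.
#' @return an `eeg_record`.
#' @export
load_recording <- function(path, format = c("auto", "edf", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else if (ext %in% c("rds", "h5r")) "rds"
              else stop("cannot guess format of ", path)
  }
  if (format == "edf") return(read_edf(path))
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_record")) stop("RDS file does not hold an eeg_record")
  rec
}

#' Save an EEG recording
#' @param rec an `eeg_record`.
#' @param path output path; extension picks the format (.edf or .rds).
#' @export
save_recording <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") write_edf(rec, path) else saveRDS(rec, path)
  invisible(path)
}

# tolerant electrode matching: "EEG Fp1-Ref", "fp1" etc. all match "Fp1"
.find_channel <- function(labels, target) {
  lab <- tolower(labels)
  tgt <- tolower(target)
  hit <- which(lab == tgt)
  if (length(hit)) return(hit[1L])
  # strip common prefixes/suffixes ("eeg fp1", "fp1-ref")
  core <- sub("^eeg[ _]*", "", lab)
  core <- sub("[-_ ]*(ref|le|av)$", "", core)
  hit <- which(core == tgt)
  if (length(hit)) return(hit[1L])
  hit <- grep(paste0("(^|[^a-z0-9])", tgt, "($|[^a-z0-9])"), lab)
  if (length(hit) == 1L) return(hit)
  NA_integer_
}

#' Re-reference frontal EEG to the bipolar Fp1-F7 / Fp2-F8 montage
#'
#' Converts a 4-electrode frontal referential recording into the two
#' bipolar derivations used throughout the pipeline. Channel-label
#' matching is case-insensitive and tolerant of common label dialects
#' ("EEG Fp1", "Fp1-Ref"). A recording already carrying the bipolar
#' labels is returned unchanged.
#'
#' @param rec an `eeg_record` containing Fp1, F7, Fp2 and F8.
#' @return a 2-channel `eeg_record` with labels `Fp1-F7`, `Fp2-F8`.
#' @export
rereference <- function(rec) {
  stopifnot(inherits(rec, "eeg_record"))
  lab <- tolower(gsub(" ", "", rec$channel_labels))
  if (all(c("fp1-f7", "fp2-f8") %in% lab)) {
    idx <- c(match("fp1-f7", lab), match("fp2-f8", lab))
    return(eeg_record(rec$data[idx, , drop = FALSE], rec$fs,
                      c("Fp1-F7", "Fp2-F8"), rec$start_time))
  }
  need <- c("Fp1", "F7", "Fp2", "F8")
  idx <- vapply(need, .find_channel, integer(1L), labels = rec$channel_labels)
  if (anyNA(idx)) {
    stop("missing required channel(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  }
  out <- rbind(rec$data[idx["Fp1"], ] - rec$data[idx["F7"], ],
               rec$data[idx["Fp2"], ] - rec$data[idx["F8"], ])
  eeg_record(out, rec$fs, c("Fp1-F7", "Fp2-F8"), rec$start_time)
}
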