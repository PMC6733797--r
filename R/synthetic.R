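# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Specification of one behavioral state's EEG
#'
#' Describes the synthetic EEG emitted while a patient occupies one RASS
#' level: the relative delta/theta/alpha weights of the colored-noise
#' base, its RMS amplitude, the burst-suppression fraction (deep coma
#' only) and the blink-transient rate (wakefulness only).
#'
#' @param rass RASS level, integer in -5..0.
#' @param delta_w,theta_w,alpha_w nonnegative spectral weights summing to 1.
#' @param amplitude burst/base RMS amplitude, uV.
#' @param suppression_frac fraction of time suppressed, in \[0,1\];
#'   only allowed for RASS -4/-5.
#' @param blink_rate blink transients per minute.
#' @param cam_positive logical delirium status attached to the state.
#' @return list of class `state_spec`.
#' @export
state_spec <- function(rass, delta_w, theta_w, alpha_w, amplitude,
                       suppression_frac = 0, blink_rate = 0,
                       cam_positive = FALSE) {
  stopifnot(rass %in% -5:0, delta_w >= 0, theta_w >= 0, alpha_w >= 0,
            suppression_frac >= 0, suppression_frac <= 1, amplitude > 0)
  s <- delta_w + theta_w + alpha_w
  if (abs(s - 1) > 1e-6) stop("spectral weights must sum to 1")
  if (suppression_frac > 0 && rass > -4L) {
    stop("burst suppression is only generated for RASS -4/-5")
  }
  structure(list(rass = as.integer(rass), delta_w = delta_w,
                 theta_w = theta_w, alpha_w = alpha_w,
                 amplitude = amplitude, suppression_frac = suppression_frac,
                 blink_rate = blink_rate, cam_positive = isTRUE(cam_positive)),
            class = "state_spec")
}

#' Default state specifications per RASS level
#'
#' A monotone spectral gradation: relative delta weight rises and alpha
#' falls from alert (0) to unarousable (-5); amplitude of slow activity
#' rises with depth; burst suppression appears at -4/-5; blink
#' transients only near the alert state. `separation` < 1 shrinks all
#' specs toward their mean, lowering the ceiling of any downstream
#' classifier.
#'
#' @param separation gradation strength in (0, 1\]; 1 = full separation.
#' @return named list of `state_spec`, names "0".."-5".
#' @export
default_state_specs <- function(separation = 1) {
  base <- list(
    `0`  = c(0.08, 0.27, 0.65, 15, 0.00, 1.0),
    `-1` = c(0.28, 0.32, 0.40, 15, 0.00, 0.0),
    `-2` = c(0.42, 0.33, 0.25, 17, 0.00, 0.0),
    `-3` = c(0.58, 0.27, 0.15, 19, 0.00, 0.0),
    `-4` = c(0.72, 0.20, 0.08, 22, 0.25, 0.0),
    `-5` = c(0.83, 0.12, 0.05, 25, 0.55, 0.0)
  )
  mid <- Reduce(`+`, base) / length(base)
  out <- lapply(names(base), function(nm) {
    v <- mid + separation * (base[[nm]] - mid)
    v[1:3] <- pmax(v[1:3], 0.01); v[1:3] <- v[1:3] / sum(v[1:3])
    supp <- if (as.integer(nm) <= -4L) max(v[5L], 0) else 0
    state_spec(as.integer(nm), v[1L], v[2L], v[3L], max(v[4L], 5),
               suppression_frac = supp,
               blink_rate = if (as.integer(nm) == 0L) base[[nm]][6L] else 0)
  })
  names(out) <- names(base)
  out
}

# colored Gaussian noise with piecewise-flat band spectrum; exact RMS.
# Synthesized directly in the frequency domain in power-of-two chunks
# (one inverse FFT each); chunk seams carry a phase discontinuity but
# identical spectra, which is immaterial for band-power/BSR structure.
.colored_noise <- function(n, fs, weights, rms) {
  chunk <- 2^max(10L, min(17L, round(log2(fs * 600))))
  pieces <- list()
  got <- 0L
  while (got < n) {
    m <- chunk
    freq <- (seq_len(m %/% 2L + 1L) - 1L) * fs / m
    amp <- numeric(length(freq))
    bands <- list(c(0.5, 4, weights[1L] / 3.5), c(4, 8, weights[2L] / 4),
                  c(8, 12, weights[3L] / 4), c(12, 18, 0.02 / 6))
    for (b in bands) {
      sel <- freq >= b[1L] & freq < b[2L]
      amp[sel] <- sqrt(b[3L])
    }
    np <- length(freq)
    X <- complex(m)
    mid <- 2:(np - 1L)
    X[mid] <- complex(real = stats::rnorm(np - 2L),
                      imaginary = stats::rnorm(np - 2L)) * amp[mid]
    X[np] <- stats::rnorm(1L) * amp[np]
    X[m + 2L - mid] <- Conj(X[mid])
    y <- Re(stats::fft(X, inverse = TRUE))
    y <- y / max(stats::sd(y), 1e-12)
    pieces[[length(pieces) + 1L]] <- y
    got <- got + m
  }
  out <- unlist(pieces)[seq_len(n)]
  out * rms / max(stats::sd(out), 1e-12)
}

# 300-ms biphasic blink transient
.blink_wave <- function(fs, amp) {
  L <- as.integer(round(0.3 * fs))
  t <- seq_len(L) / L
  amp * sin(2 * pi * t) * (0.5 - 0.5 * cos(2 * pi * t))
}

# alternating burst/suppression gate in [0,1] with soft 0.1-s ramps.
# Suppression epochs are drawn U(2,10) s; burst lengths are scaled from
# U(1,5) s so the expected suppressed fraction matches `frac` (keeping
# suppression epochs long relative to the envelope smoothing window).
.suppression_gate <- function(n, fs, frac) {
  burst_scale <- (6 * (1 - frac) / frac) / 3
  mean_cycle <- 3 * burst_scale + 6
  n_ep <- 2L * (as.integer(2 * n / (fs * mean_cycle)) + 8L)
  first_burst <- stats::runif(1) > frac
  durs <- ifelse(seq_len(n_ep) %% 2L == (if (first_burst) 1L else 0L),
                 stats::runif(n_ep, 1, 5) * burst_scale,
                 stats::runif(n_ep, 2, 10))
  vals <- rep_len(if (first_burst) c(1, 0) else c(0, 1), n_ep)
  gate <- rep(vals, pmax(1L, as.integer(round(durs * fs))))
  if (length(gate) < n) gate <- c(gate, rep(gate[length(gate)], n))
  gate <- gate[seq_len(n)]
  k <- max(1L, as.integer(round(0.1 * fs)))
  sm <- as.numeric(stats::filter(gate, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- gate[is.na(sm)]
  sm
}

#' Generate a two-channel EEG signal for one behavioral state
#'
#' Colored-noise mixture shaped by the state's delta/theta/alpha
#' weights and scaled to its RMS amplitude; the two channels share a
#' common component (correlation ~0.7). States with
#' `suppression_frac > 0` alternate bursts at the spec amplitude with
#' suppression epochs of ~1 uV noise occupying the stated fraction of
#' time. Blink transients (300 ms biphasic, 80-150 uV, frontally
#' dominant) occur at `blink_rate` per minute.
#'
#' @param spec a [state_spec()].
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; same seed gives identical signals.
#' @param channel_labels labels of the two output channels.
#' @return an `eeg_record` with 2 channels.
#' @export
generate_state_signal <- function(spec, duration, fs = 250, seed = 1,
                                  channel_labels = c("Fp1-F7", "Fp2-F8")) {
  stopifnot(inherits(spec, "state_spec"), duration > 0)
  .with_seed(seed, {
    n <- as.integer(round(duration * fs))
    w <- c(spec$delta_w, spec$theta_w, spec$alpha_w)
    rho <- 0.7
    shared <- .colored_noise(n, fs, w, 1)
    ch <- vapply(1:2, function(i) {
      own <- .colored_noise(n, fs, w, 1)
      mix <- sqrt(rho) * shared + sqrt(1 - rho) * own
      mix / stats::sd(mix) * spec$amplitude
    }, numeric(n))
    ch <- t(ch)
    if (spec$suppression_frac > 0) {
      gate <- .suppression_gate(n, fs, spec$suppression_frac)
      for (i in 1:2) {
        floor_noise <- .colored_noise(n, fs, w, 1)
        ch[i, ] <- ch[i, ] * gate + floor_noise * (1 - gate)
      }
    }
    if (spec$blink_rate > 0) {
      n_blinks <- stats::rpois(1, spec$blink_rate * duration / 60)
      if (n_blinks > 0) {
        L <- as.integer(round(0.3 * fs))
        starts <- sort(sample.int(max(n - L, 1L), n_blinks, replace = TRUE))
        for (s in starts) {
          wv <- .blink_wave(fs, stats::runif(1, 80, 150))
          idx <- s:(s + length(wv) - 1L)
          ch[1L, idx] <- ch[1L, idx] + wv
          ch[2L, idx] <- ch[2L, idx] + 0.8 * wv
        }
      }
    }
    eeg_record(ch, fs, channel_labels)
  })
}

#' Inject ground-truth artifacts into a recording
#'
#' Adds events designed to trip the four artifact rules: `spike`
#' (smooth transient exceeding 1000 uV), `jump` (a step change of more
#' than 900 uV within 0.1 s while staying under the amplitude ceiling),
#' `flatline` (signal replaced by ~0.05 uV noise, std < 0.2 uV) and
#' `machine_tone` (a single-frequency sinusoid producing a
#' staircase-like spectral step). Events are placed without overlap;
#' their true intervals are returned for detector validation.
#'
#' @param rec an `eeg_record`.
#' @param menu character vector of event kinds to draw from.
#' @param rate events per minute.
#' @param seed integer seed.
#' @return the modified `eeg_record`, with attribute `artifact_truth`:
#'   data.frame (onset_s, duration_s, kind).
#' @export
inject_artifacts <- function(rec,
                             menu = c("spike", "flatline", "machine_tone"),
                             rate = 1, seed = 1) {
  stopifnot(inherits(rec, "eeg_record"))
  dur <- record_duration(rec)
  n_events <- as.integer(round(rate * dur / 60))
  truth <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (n_events == 0L) {
    attr(rec, "artifact_truth") <- truth
    return(rec)
  }
  ev_len <- c(spike = 0.4, jump = 1.0, flatline = 9.0, machine_tone = 5.0)
  .with_seed(seed, {
    kinds <- sample(menu, n_events, replace = TRUE)
    slot <- max(ev_len[menu]) + 4            # event plus one clean segment
    n_slots <- floor(dur / slot)
    if (n_slots < n_events) stop("artifact rate too high to place non-overlapping events")
    slots <- sort(sample.int(n_slots, n_events))
    fs <- rec$fs
    for (e in seq_len(n_events)) {
      kind <- kinds[e]
      len <- ev_len[[kind]]
      onset <- (slots[e] - 1) * slot + stats::runif(1, 0, slot - len - 0.2)
      i0 <- as.integer(round(onset * fs)) + 1L
      i1 <- min(ncol(rec$data), i0 + as.integer(round(len * fs)) - 1L)
      idx <- i0:i1
      if (kind == "spike") {
        t <- seq_along(idx) / length(idx)
        wave <- stats::runif(1, 1300, 2200) * sin(pi * t)^2
        rec$data[1L, idx] <- rec$data[1L, idx] + wave
      } else if (kind == "jump") {
        # square pulse below the 1000-uV ceiling but far above the jump rule
        rec$data[1L, idx] <- rec$data[1L, idx] + 950
      } else if (kind == "flatline") {
        for (c in seq_len(nrow(rec$data))) {
          rec$data[c, idx] <- stats::rnorm(length(idx), 0, 0.05)
        }
      } else if (kind == "machine_tone") {
        f0 <- stats::runif(1, 14.5, 19)
        tone <- 28 * sin(2 * pi * f0 * (seq_along(idx) / fs))
        rec$data[1L, idx] <- rec$data[1L, idx] + tone
        rec$data[2L, idx] <- rec$data[2L, idx] + tone
      }
      truth[nrow(truth) + 1L, ] <- list(onset, len, kind)
    }
    attr(rec, "artifact_truth") <- truth
    rec
  })
}

#' Generate a synthetic ICU cohort
#'
#' Per-patient piecewise-constant RASS schedules whose transitions span
#' all six levels, nurse/technician RASS assessments on a ~2-h jittered
#' cadence, a CAM-ICU assessment on a ~24-h cadence (at least one per
#' patient), and delirium status drawn from a logistic link on the
#' patient's mean relative-delta weight. Signals are materialized
#' lazily, one patient at a time, with [cohort_record()].
#'
#' @param n_patients number of patients (>= 2).
#' @param hours_per_patient recording duration per patient, hours.
#' @param label_gradation `"strong"` (full spectral separation) or
#'   `"moderate"` (specs shrunk halfway toward their mean).
#' @param seed integer master seed; the cohort is a pure function of it.
#' @param fs raw sampling rate, Hz.
#' @param artifact_rate injected artifact events per minute (0 = none).
#' @param cam_link_gain slope of the logistic link from mean delta
#'   weight to delirium probability.
#' @return list of class `synth_cohort`.
#' @export
generate_cohort <- function(n_patients, hours_per_patient = 6,
                            label_gradation = c("strong", "moderate"),
                            seed = 1, fs = 250, artifact_rate = 0,
                            cam_link_gain = 10) {
  label_gradation <- match.arg(label_gradation)
  if (n_patients < 2L) stop("need at least 2 patients")
  sep <- if (label_gradation == "strong") 1 else 0.5
  specs <- default_state_specs(separation = sep)
  dur_s <- hours_per_patient * 3600
  .with_seed(seed, {
    pat_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    patients <- lapply(seq_len(n_patients), function(i) {
      .with_seed(pat_seeds[i], {
        # random-walk level path, blocks of 40-80 min
        lev <- sample(-5:0, 1)
        t0 <- 0; sched <- NULL
        while (t0 < dur_s) {
          len <- round(stats::runif(1, 40, 80)) * 60   # whole-second blocks
          sched <- rbind(sched, data.frame(start = t0,
                                           end = min(t0 + len, dur_s),
                                           rass = lev))
          t0 <- t0 + len
          step <- sample(c(-2L, -1L, 1L, 2L), 1)
          lev <- max(-5L, min(0L, lev + step))
        }
        mean_dw <- mean(vapply(sched$rass, function(l)
          specs[[as.character(l)]]$delta_w, numeric(1L)))
        cam_pos <- stats::runif(1) <
          stats::plogis(cam_link_gain * (mean_dw - mean(vapply(specs,
            function(s) s$delta_w, numeric(1L)))))
        level_at <- function(tt) sched$rass[findInterval(tt, sched$start)]
        # nurse RASS every ~2 h, technician every ~4 h with +/-1 noise
        n_times <- seq(3600, dur_s - 600, by = 7200) +
          stats::runif(length(seq(3600, dur_s - 600, by = 7200)), -900, 900)
        n_times <- pmax(2100, pmin(dur_s - 2100, n_times))
        t_times <- seq(5400, dur_s - 600, by = 14400) +
          stats::runif(length(seq(5400, dur_s - 600, by = 14400)), -900, 900)
        t_times <- pmax(2100, pmin(dur_s - 2100, t_times))
        t_vals <- vapply(t_times, level_at, integer(1L)) +
          sample(c(-1L, 0L, 0L, 1L), length(t_times), replace = TRUE)
        cam_time <- stats::runif(1, 1800, dur_s - 1800)
        asm <- assessments(
          time = c(n_times, t_times, cam_time),
          kind = c(rep("RASS", length(n_times) + length(t_times)), "CAM-ICU"),
          value = c(vapply(n_times, level_at, integer(1L)),
                    pmax(-5L, pmin(0L, t_vals)),
                    as.integer(cam_pos)),
          rater = c(rep("nurse", length(n_times)),
                    rep("technician", length(t_times)), "nurse"),
          patient = i
        )
        list(id = i, schedule = sched, assessments = asm,
             cam_positive = cam_pos, seed = pat_seeds[i])
      })
    })
    structure(list(patients = patients, specs = specs, fs = fs, seed = seed,
                   hours = hours_per_patient, artifact_rate = artifact_rate),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d patients x %g h @ %g Hz (seed %d)\n",
              length(x$patients), x$hours, x$fs, x$seed))
  invisible(x)
}

#' Materialize one patient's raw recording
#'
#' Builds the 4-electrode referential recording (Fp1, F7, Fp2, F8 at the
#' raw sampling rate) for one cohort patient from their state schedule.
#' A shared reference signal is added to each electrode pair so that the
#' bipolar derivations recover the generated state signals exactly.
#' Deterministic in the cohort seed.
#'
#' @param cohort a `synth_cohort`.
#' @param i patient index.
#' @param montage `"referential"` (4 electrodes with a shared reference)
#'   or `"bipolar"` (the two derivations directly; cheaper, used by the
#'   training pipeline since the reference cancels exactly anyway).
#' @return an `eeg_record` (4 channels referential, 2 bipolar);
#'   attribute `artifact_truth` present when the cohort was built with
#'   `artifact_rate > 0`.
#' @export
cohort_record <- function(cohort, i,
                          montage = c("referential", "bipolar")) {
  montage <- match.arg(montage)
  stopifnot(inherits(cohort, "synth_cohort"))
  p <- cohort$patients[[i]]
  fs <- cohort$fs
  segs <- lapply(seq_len(nrow(p$schedule)), function(b) {
    blk <- p$schedule[b, ]
    spec <- cohort$specs[[as.character(blk$rass)]]
    generate_state_signal(spec, blk$end - blk$start, fs,
                          seed = p$seed + b)$data
  })
  bip <- do.call(cbind, segs)
  rec2 <- eeg_record(bip, fs, c("Fp1-F7", "Fp2-F8"))
  if (cohort$artifact_rate > 0) {
    rec2 <- inject_artifacts(rec2, rate = cohort$artifact_rate,
                             seed = p$seed + 1000L)
  }
  if (montage == "bipolar") return(rec2)
  truth <- attr(rec2, "artifact_truth")
  n <- ncol(rec2$data)
  # the shared reference cancels exactly in the bipolar derivations, so
  # it is synthesized at a quarter rate and linearly interpolated
  make_ref <- function(sd_seed) {
    .with_seed(sd_seed, {
      lo <- .colored_noise(ceiling(n / 4) + 1L, fs / 4, c(0.4, 0.3, 0.3), 15)
      stats::approx(seq_along(lo), lo, xout = 1 + (seq_len(n) - 1L) / 4)$y
    })
  }
  ref1 <- make_ref(p$seed + 777L)
  ref2 <- make_ref(p$seed + 778L)
  out <- eeg_record(rbind(ref1 + rec2$data[1L, ], ref1,
                          ref2 + rec2$data[2L, ], ref2),
                    fs, c("Fp1", "F7", "Fp2", "F8"))
  attr(out, "artifact_truth") <- truth
  out
}

#' Ground-truth RASS level of a cohort patient at a time
#' @param cohort a `synth_cohort`.
#' @param i patient index.
#' @param time seconds.
#' @return integer RASS level.
#' @export
cohort_true_rass <- function(cohort, i, time) {
  sched <- cohort$patients[[i]]$schedule
  sched$rass[findInterval(time, sched$start)]
}
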