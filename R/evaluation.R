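.check_rass_pairs <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(!(y_true %in% -5:0)) || any(!(y_pred %in% -5:0))) {
    stop("RASS values must lie in -5..0")
  }
}

#' Balanced mean absolute error between RASS levels
#'
#' Class-weighted MAE: the mean absolute error within each observed
#' true class, combined with weights proportional to 1/n_c (summing to
#' 1). Invariant to duplicating any class's samples.
#'
#' @param y_true,y_pred integer RASS levels in -5..0.
#' @return nonnegative scalar.
#' @export
balanced_mae <- function(y_true, y_pred) {
  .check_rass_pairs(y_true, y_pred)
  err <- abs(y_true - y_pred)
  cls <- sort(unique(y_true))
  per_class <- vapply(cls, function(c) mean(err[y_true == c]), numeric(1L))
  mean(per_class)
}

#' Balanced accuracy within a tolerance of RASS levels
#'
#' Class-weighted fraction of predictions within `tol` levels of truth
#' (tol = 1 gives the "within one level" accuracy).
#'
#' @param y_true,y_pred integer RASS levels in -5..0.
#' @param tol allowed absolute difference (0 or 1).
#' @return value in \[0, 1\].
#' @export
tolerance_accuracy <- function(y_true, y_pred, tol = 1L) {
  .check_rass_pairs(y_true, y_pred)
  stopifnot(tol %in% c(0L, 1L))
  hit <- abs(y_true - y_pred) <= tol
  cls <- sort(unique(y_true))
  mean(vapply(cls, function(c) mean(hit[y_true == c]), numeric(1L)))
}

#' Coma-vs-awake discrimination AUC
#'
#' Rank-based (Mann-Whitney) AUC of the z-score for discriminating
#' "awake" (RASS -1 or 0) from "coma" (RASS -5 or -4), discarding
#' intermediate levels. Ties count 1/2. Larger z is expected for awake.
#'
#' @param y_true integer RASS levels.
#' @param z numeric scores.
#' @return AUC in \[0, 1\].
#' @export
coma_awake_auc <- function(y_true, z) {
  stopifnot(length(y_true) == length(z))
  grp <- ifelse(y_true %in% c(-5L, -4L), "coma",
                ifelse(y_true %in% c(-1L, 0L), "awake", NA))
  keep <- !is.na(grp)
  grp <- grp[keep]; z <- z[keep]
  n1 <- sum(grp == "awake"); n0 <- sum(grp == "coma")
  if (n1 == 0L || n0 == 0L) stop("need both coma and awake samples")
  r <- rank(z)
  (sum(r[grp == "awake"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Probability calibration curve and error
#'
#' Equal-width binning of predicted probabilities; the calibration
#' error is the mean absolute distance to the diagonal over non-empty
#' bins.
#'
#' @param p_pred probabilities in \[0,1\].
#' @param y binary outcomes.
#' @param n_bins number of equal-width bins.
#' @return list: `curve` (data.frame bin_mid, mean_pred, mean_obs, n)
#'   and `error`.
#' @export
calibration <- function(p_pred, y, n_bins = 10L) {
  stopifnot(all(p_pred >= 0 & p_pred <= 1), all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) stop("need both positive and negative labels")
  bin <- pmin(n_bins, floor(p_pred * n_bins) + 1L)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(bin_mid = (b - 0.5) / n_bins, mean_pred = mean(p_pred[sel]),
               mean_obs = mean(y[sel]), n = sum(sel))
  })
  curve <- do.call(rbind, rows)
  list(curve = curve, error = mean(abs(curve$mean_pred - curve$mean_obs)))
}

#' Fit a probability recalibration mapping
#'
#' Learns a monotone mapping from raw to calibrated probabilities on a
#' validation set, applied out-of-fold. Isotonic regression is the
#' default; a logistic (Platt-style) alternative is available.
#'
#' @param p_val validation-set predicted probabilities.
#' @param y_val validation-set outcomes (0/1).
#' @param method `"isotonic"` or `"logistic"`.
#' @return a function mapping probabilities to recalibrated values.
#' @export
recalibrate <- function(p_val, y_val, method = c("isotonic", "logistic")) {
  method <- match.arg(method)
  if (method == "isotonic") {
    o <- order(p_val)
    iso <- stats::isoreg(p_val[o], y_val[o])
    xs <- iso$x; ys <- iso$yf
    function(p) {
      stats::approx(xs, ys, xout = p, rule = 2L, ties = mean)$y
    }
  } else {
    eps <- 1e-6
    lo <- stats::qlogis(pmin(pmax(p_val, eps), 1 - eps))
    fit <- stats::glm(y_val ~ lo, family = stats::binomial())
    function(p) {
      lp <- stats::qlogis(pmin(pmax(p, eps), 1 - eps))
      as.numeric(stats::predict(fit, data.frame(lo = lp), type = "response"))
    }
  }
}

#' Pair technician and nurse assessments
#'
#' For each technician RASS assessment, finds the temporally closest
#' nurse assessment of the same patient; pairs further apart than
#' `max_gap` (default 4 h) are discarded. Nurse assessments may be
#' reused across pairs.
#'
#' @param tech,nurse `assessment_table`s with patient identity.
#' @param max_gap maximum pairing gap in seconds.
#' @return list: `pairs` (data.frame patient, tech_time, nurse_time,
#'   gap, tech_value, nurse_value, abs_diff) and `per_patient`
#'   (data.frame patient, mean_abs_diff, n).
#' @export
pair_raters <- function(tech, nurse, max_gap = 14400) {
  stopifnot(max_gap > 0)
  tech <- tech[tech$kind == "RASS", , drop = FALSE]
  nurse <- nurse[nurse$kind == "RASS", , drop = FALSE]
  pairs <- NULL
  for (i in seq_len(nrow(tech))) {
    cand <- nurse[!is.na(nurse$patient) & nurse$patient == tech$patient[i], ,
                  drop = FALSE]
    if (!nrow(cand)) next
    gaps <- abs(cand$time - tech$time[i])
    j <- which.min(gaps)
    if (gaps[j] > max_gap) next
    pairs <- rbind(pairs, data.frame(
      patient = tech$patient[i], tech_time = tech$time[i],
      nurse_time = cand$time[j], gap = gaps[j],
      tech_value = tech$value[i], nurse_value = cand$value[j],
      abs_diff = abs(tech$value[i] - cand$value[j])))
  }
  if (is.null(pairs)) {
    pairs <- data.frame(patient = numeric(0), tech_time = numeric(0),
                        nurse_time = numeric(0), gap = numeric(0),
                        tech_value = integer(0), nurse_value = integer(0),
                        abs_diff = numeric(0))
  }
  per_patient <- if (nrow(pairs)) {
    agg <- stats::aggregate(abs_diff ~ patient, data = pairs, FUN = mean)
    cnt <- stats::aggregate(abs_diff ~ patient, data = pairs, FUN = length)
    data.frame(patient = agg$patient, mean_abs_diff = agg$abs_diff,
               n = cnt$abs_diff)
  } else {
    data.frame(patient = numeric(0), mean_abs_diff = numeric(0),
               n = integer(0))
  }
  list(pairs = pairs, per_patient = per_patient)
}

#' Tracking delay after a state transition
#'
#' Given a per-step prediction trace over two concatenated 9.5-min
#' windows whose true levels differ by more than one (RASS1 then
#' RASS2), the delay is the time from the concatenation point to the
#' first step whose predicted level lies within RASS2 +/- 1. Traces
#' that never reach the target band are censored at the length of the
#' second window.
#'
#' @param times step times in seconds (monotone increasing).
#' @param levels predicted RASS level per step.
#' @param junction_time concatenation time (s).
#' @param rass_from,rass_to true levels before/after the junction.
#' @return list of class `delay_result`: `rass_from`, `rass_to`,
#'   `delay` (s, `NA` when censored), `censored`.
#' @export
measure_delay <- function(times, levels, junction_time, rass_from, rass_to) {
  if (abs(rass_from - rass_to) <= 1) {
    stop("delay is defined only for transitions of more than one level")
  }
  after <- which(times >= junction_time)
  if (!length(after)) stop("no prediction steps after the junction")
  hit <- after[abs(levels[after] - rass_to) <= 1]
  if (length(hit)) {
    structure(list(rass_from = rass_from, rass_to = rass_to,
                   delay = times[hit[1L]] - junction_time, censored = FALSE),
              class = "delay_result")
  } else {
    structure(list(rass_from = rass_from, rass_to = rass_to,
                   delay = NA_real_, censored = TRUE,
                   censor_time = max(times) - junction_time),
              class = "delay_result")
  }
}

#' Delay experiment on a trained model
#'
#' Concatenates two 9.5-min windows with different true levels, runs
#' the sliding prediction (4-s step, trailing context), and measures
#' the delay to reach RASS2 +/- 1 after the junction.
#'
#' @param model a `sedation_model` (task "rass").
#' @param rec1,rec2 `eeg_record`s at 62.5 Hz (9.5 min each).
#' @param rass_from,rass_to their true levels (|difference| > 1).
#' @param context_steps trailing steps averaged per prediction.
#' @return a `delay_result`.
#' @export
model_delay <- function(model, rec1, rec2, rass_from, rass_to,
                        context_steps = 142L) {
  cat_rec <- eeg_record(cbind(rec1$data, rec2$data), rec1$fs,
                        rec1$channel_labels)
  tr <- track_trace(model, cat_rec, context_steps = context_steps)
  junction <- record_duration(rec1)
  measure_delay(tr$time_s, tr$rass_pred, junction, rass_from, rass_to)
}

#' Dunn's post hoc test
#'
#' Pairwise rank-sum comparisons after a Kruskal-Wallis test, using the
#' joint ranking with tie correction; two-sided p-values with
#' Bonferroni adjustment.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return data.frame: group1, group2, z, p, p_adj.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(groups)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  combs <- utils::combn(lev, 2L)
  res <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_r[[i]] - mean_r[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                    z = res["z", ], p = res["p", ])
  out$p_adj <- pmin(1, out$p * nrow(out))
  out
}

#' Compare per-patient metric distributions across methods
#'
#' Kruskal-Wallis one-way ANOVA across methods, Dunn's two-sided post
#' hoc pairwise tests with Bonferroni correction, and seeded percentile
#' bootstrap confidence intervals of each group median.
#'
#' @param metric_lists named list of numeric vectors (one per method).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list: `kw` (htest), `pairwise` (Dunn table), `ci`
#'   (data.frame method, median, lo, hi).
#' @export
compare_methods <- function(metric_lists, n_boot = 1000L, conf = 0.95,
                            seed = 1L) {
  if (length(metric_lists) < 2L) stop("need at least two methods")
  if (any(vapply(metric_lists, length, integer(1L)) < 2L)) {
    stop("each method needs at least two values")
  }
  values <- unlist(metric_lists, use.names = FALSE)
  groups <- rep(names(metric_lists),
                vapply(metric_lists, length, integer(1L)))
  kw <- stats::kruskal.test(values, as.factor(groups))
  pw <- dunn_test(values, groups)
  alpha <- 1 - conf
  ci <- .with_seed(seed, {
    do.call(rbind, lapply(names(metric_lists), function(nm) {
      x <- metric_lists[[nm]]
      meds <- vapply(seq_len(n_boot), function(b) {
        stats::median(sample(x, length(x), replace = TRUE))
      }, numeric(1L))
      data.frame(method = nm, median = stats::median(x),
                 lo = stats::quantile(meds, alpha / 2, names = FALSE),
                 hi = stats::quantile(meds, 1 - alpha / 2, names = FALSE))
    }))
  })
  list(kw = kw, pairwise = pw, ci = ci)
}
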