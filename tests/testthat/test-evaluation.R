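test_that("balanced MAE matches hand-computed values", {
  expect_equal(balanced_mae(c(-3, -2, 0), c(-3, -2, 0)), 0)
  # every prediction off by one: 1.0 regardless of class mix
  expect_equal(balanced_mae(c(-5, -5, -5, -1), c(-4, -4, -4, 0)), 1)
  # unequal class sizes: classes weighted equally
  expect_equal(balanced_mae(c(-5, -5, -5, 0), c(-5, -5, -5, -2)), 1)
  expect_error(balanced_mae(integer(0), integer(0)), "empty")
  expect_error(balanced_mae(c(-6), c(0)), "-5..0")
})

test_that("tolerance accuracy matches hand-computed values", {
  expect_equal(tolerance_accuracy(c(-3, 0), c(-3, 0), 0L), 1)
  expect_equal(tolerance_accuracy(c(-3, 0), c(-2, -1), 0L), 0)
  expect_equal(tolerance_accuracy(c(-3, 0), c(-2, -1), 1L), 1)
  expect_equal(tolerance_accuracy(c(-5, 0), c(-4, -2), 1L), 0.5)
})

test_that("balanced metrics are invariant to duplicating a class", {
  y <- c(-5, -5, -3, 0); p <- c(-4, -5, -1, -2)
  y2 <- c(y, rep(-5, 10)); p2 <- c(p, rep(-4, 5), rep(-5, 5))
  # duplicated class keeps its within-class error profile
  expect_equal(balanced_mae(c(y, -5, -5), c(p, -4, -5)),
               balanced_mae(y, p))
  expect_equal(tolerance_accuracy(c(y, -5, -5), c(p, -4, -5), 1L),
               tolerance_accuracy(y, p, 1L))
})

test_that("coma-vs-awake AUC matches pair enumeration and conventions", {
  expect_equal(coma_awake_auc(c(-5, -4, -1, 0), c(0, 1, 2, 3)), 1)
  expect_equal(coma_awake_auc(c(-5, -4, -1, 0), rep(1, 4)), 0.5)
  expect_equal(coma_awake_auc(c(-5, -5, 0, 0), c(1, 2, 1.5, 3)), 0.75)
  # intermediate levels are discarded
  expect_equal(coma_awake_auc(c(-5, -3, -2, 0), c(5, -10, 10, 6)), 1)
  expect_error(coma_awake_auc(c(-5, -4), c(1, 2)), "both")
})

test_that("AUC antisymmetry holds for random score vectors", {
  set.seed(14)
  for (i in 1:25) {
    y <- c(rep(-5, 5), rep(-4, 3), rep(-1, 4), rep(0, 6))
    z <- sample(c(rnorm(15), rep(0.3, 3)))
    expect_equal(coma_awake_auc(y, z) + coma_awake_auc(y, -z), 1)
  }
})

test_that("calibration error matches single-bin arithmetic", {
  y <- rep(c(0, 1), 50)
  expect_equal(calibration(as.numeric(y), y)$error, 0)
  expect_equal(calibration(rep(0.5, 100), y)$error, 0)
  expect_equal(calibration(rep(0.9, 100), y)$error, 0.4)
  expect_error(calibration(rep(0.5, 4), rep(1, 4)), "positive and negative")
})

test_that("isotonic recalibration straightens a distorted probability", {
  set.seed(15)
  p_true <- runif(400)
  y <- as.integer(runif(400) < p_true)
  p_raw <- p_true^3                       # badly mis-calibrated
  before <- calibration(p_raw, y)$error
  f <- recalibrate(p_raw, y)
  after <- calibration(pmin(pmax(f(p_raw), 0), 1), y)$error
  expect_lt(after, before)
  expect_true(all(diff(f(seq(0, 1, 0.05))) >= -1e-9))  # monotone mapping
})

test_that("rater pairing takes the closest nurse within 4 h", {
  tech <- assessments(0, "RASS", -2, rater = "technician", patient = 1)
  nurse <- assessments(c(3500, 20000), "RASS", c(-2, 0),
                       rater = "nurse", patient = 1)
  pr <- pair_raters(tech, nurse)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$nurse_time, 3500)
  expect_equal(pr$pairs$abs_diff, 0)
  # a gap of 14401 s is more than 4 h: excluded
  nurse_far <- assessments(14401, "RASS", 0, rater = "nurse", patient = 1)
  expect_equal(nrow(pair_raters(tech, nurse_far)$pairs), 0L)
  # boundary: exactly 4 h is kept
  nurse_edge <- assessments(14400, "RASS", 0, rater = "nurse", patient = 1)
  expect_equal(nrow(pair_raters(tech, nurse_edge)$pairs), 1L)
  # no nurse assessments at all
  empty <- assessments(numeric(0), character(0), integer(0))
  expect_equal(nrow(pair_raters(tech, empty)$pairs), 0L)
})

test_that("rater pairing respects patient identity and order invariance", {
  tech <- assessments(c(100, 5000), "RASS", c(-3, -1),
                      rater = "technician", patient = c(1, 2))
  nurse <- assessments(c(200, 4500, 90), "RASS", c(-3, 0, -5),
                       rater = "nurse", patient = c(1, 2, 2))
  pr <- pair_raters(tech, nurse)
  expect_equal(pr$pairs$nurse_time, c(200, 4500))
  shuf <- nurse[c(3, 1, 2), ]
  pr2 <- pair_raters(tech, shuf)
  expect_equal(sort(pr2$pairs$nurse_time), sort(pr$pairs$nurse_time))
  expect_true(all(pr$pairs$gap <= 14400))
  expect_equal(pr$per_patient$mean_abs_diff, c(0, 1))
})

test_that("delay measurement matches analytic crossing times", {
  # predictor that steps to the target level exactly at the junction
  times <- seq(4, 1140, by = 4)
  lev <- ifelse(times < 570, 0L, -4L)
  d0 <- measure_delay(times, lev, 570, 0L, -4L)
  expect_equal(d0$delay, 0, tolerance = 4)
  expect_false(d0$censored)
  # z ramp: enters the RASS2 +/- 1 band (level <= -3) when z crosses
  # below theta_3 = 0, analytically (2.5 - 0) / 0.1 = 25 s after junction
  th <- c(-2, -1, 0, 1, 2)
  z <- ifelse(times < 570, 2.5, 2.5 - 0.1 * (times - 570))
  lv <- discretize(z, th)
  d1 <- measure_delay(times, lv, 570, 0L, -4L)
  expect_gte(d1$delay, 25)
  expect_lte(d1$delay, 25 + 4)             # within one 4-s step
  # never reaching the band: censored, not a number
  lv2 <- rep(0L, length(times))
  d2 <- measure_delay(times, lv2, 570, 0L, -4L)
  expect_true(d2$censored)
  expect_true(is.na(d2$delay))
  expect_error(measure_delay(times, lv, 570, -2L, -3L), "more than one")
})

test_that("delays grow with the distance the z-score must travel", {
  times <- seq(4, 1140, by = 4)
  th <- c(-2, -1, 0, 1, 2)
  slope <- 0.02
  delays <- vapply(2:5, function(drop) {
    target <- 0L - drop
    z_to <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)[target + 6L]
    z <- ifelse(times < 570, 2.5, pmax(z_to, 2.5 - slope * (times - 570)))
    d <- measure_delay(times, discretize(z, th), 570, 0L, target)
    d$delay
  }, numeric(1L))
  expect_true(all(diff(delays) > 0))
})

test_that("Kruskal-Wallis + Dunn flag exactly the shifted group", {
  groups <- list(a = 1:20, b = 101:120, c = 1:20)
  res <- compare_methods(groups, n_boot = 100, seed = 3)
  expect_lt(res$kw$p.value, 1e-6)
  sig <- res$pairwise$p_adj < 0.05
  expect_equal(sig[order(paste(res$pairwise$group1, res$pairwise$group2))],
               c(TRUE, FALSE, TRUE))   # a-b, a-c, b-c
  # identical groups: KW p ~ 1, nothing significant
  same <- compare_methods(list(x = 1:10, y = 1:10), n_boot = 50, seed = 1)
  expect_gt(same$kw$p.value, 0.9)
  expect_true(all(same$pairwise$p_adj > 0.9))
})

test_that("bootstrap CI of a constant list has zero width", {
  res <- compare_methods(list(a = rep(2, 6), b = rep(5, 6)),
                         n_boot = 100, seed = 2)
  expect_equal(res$ci$lo, res$ci$median)
  expect_equal(res$ci$hi, res$ci$median)
  expect_error(compare_methods(list(a = 1:3)), "two methods")
  expect_error(compare_methods(list(a = 1:3, b = 2)), "two values")
})
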