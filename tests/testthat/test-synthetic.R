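test_that("state specs validate their invariants", {
  expect_error(state_spec(-1L, 0.5, 0.5, 0.5, 10), "sum to 1")
  expect_error(state_spec(-2L, 0.5, 0.3, 0.2, 10, suppression_frac = 0.3),
               "-4/-5")
  expect_silent(state_spec(-5L, 0.8, 0.15, 0.05, 25, suppression_frac = 0.5))
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- default_state_specs()[["-3"]]
  a <- generate_state_signal(sp, 20, fs = 62.5, seed = 77)
  b <- generate_state_signal(sp, 20, fs = 62.5, seed = 77)
  expect_identical(a$data, b$data)
  c <- generate_state_signal(sp, 20, fs = 62.5, seed = 78)
  expect_gt(max(abs(c$data - a$data)), 1)
})

test_that("generated spectra match the spec weights (blink/suppression-free)", {
  for (lev in as.character(0:-5)) {
    sp <- default_state_specs()[[lev]]
    sp$blink_rate <- 0; sp$suppression_frac <- 0
    class(sp) <- "state_spec"
    rec <- generate_state_signal(sp, 60, fs = 62.5, seed = 3)
    b <- band_powers(rec$data, 62.5, win_sec = 4)
    expect_lt(abs(b$rdelta - sp$delta_w), 0.1)
    expect_lt(abs(b$rtheta - sp$theta_w), 0.1)
    expect_lt(abs(b$ralpha - sp$alpha_w), 0.1)
  }
})

test_that("relative delta power rises monotonically from alert to coma", {
  rd <- vapply(as.character(0:-5), function(lev) {
    rec <- generate_state_signal(default_state_specs()[[lev]], 120,
                                 fs = 62.5, seed = 5)
    band_powers(rec$data, 62.5, win_sec = 4)$rdelta
  }, numeric(1L))
  expect_true(all(diff(rd) > 0))
})

test_that("awake spec yields alpha-dominant features", {
  rec <- generate_state_signal(default_state_specs()[["0"]], 60,
                               fs = 62.5, seed = 9)
  b <- band_powers(rec$data, 62.5, win_sec = 4)
  expect_gt(b$ralpha, b$rdelta)
})

test_that("coma spec burst suppression is recovered by the BSR", {
  spec <- state_spec(-5L, 0.83, 0.12, 0.05, 25, suppression_frac = 0.7)
  rec <- generate_state_signal(spec, 900, fs = 62.5, seed = 13)
  expect_equal(burst_suppression_ratio(rec), 0.7, tolerance = 0.05)
})

test_that("zero artifact rate leaves the record unchanged", {
  sp <- default_state_specs()[["-2"]]
  rec <- generate_state_signal(sp, 60, fs = 62.5, seed = 2)
  out <- inject_artifacts(rec, rate = 0, seed = 1)
  expect_identical(out$data, rec$data)
  expect_equal(nrow(attr(out, "artifact_truth")), 0L)
})

test_that("injected spikes are caught by the amplitude rule", {
  sp <- default_state_specs()[["-2"]]
  rec <- generate_state_signal(sp, 600, fs = 62.5, seed = 41)
  rec <- inject_artifacts(rec, menu = "spike", rate = 1, seed = 42)
  truth <- attr(rec, "artifact_truth")
  expect_equal(nrow(truth), 10L)
  batch <- segment(rec, "contiguous")
  m <- detect_artifacts(batch)
  hits <- vapply(seq_len(nrow(truth)), function(r) {
    covered <- which(batch$segment_times >= truth$onset_s[r] - 4 &
                     batch$segment_times <= truth$onset_s[r] + truth$duration_s[r])
    any(m$per_rule[covered, "amplitude"])
  }, logical(1L))
  expect_gte(sum(hits), 9L)
})

test_that("an 8-s flatline flags two contiguous segments", {
  sp <- default_state_specs()[["-2"]]
  rec <- generate_state_signal(sp, 60, fs = 62.5, seed = 43)
  # place the flatline by hand on segment boundaries: samples in (16, 24] s
  idx <- (16 * 62.5 + 1):(24 * 62.5)
  set.seed(1)
  rec$data[, idx] <- rnorm(2 * length(idx), 0, 0.05)
  m <- detect_artifacts(segment(rec, "contiguous"))
  expect_equal(which(m$per_rule[, "flatline"]), c(5L, 6L))
})

test_that("artifact placement fails cleanly when the rate is too high", {
  sp <- default_state_specs()[["-2"]]
  rec <- generate_state_signal(sp, 60, fs = 62.5, seed = 44)
  expect_error(inject_artifacts(rec, rate = 20, seed = 1), "rate too high")
})

test_that("cohorts have the stated assessment cadence and determinism", {
  coh <- generate_cohort(3, hours_per_patient = 6, seed = 19)
  expect_length(coh$patients, 3L)
  for (p in coh$patients) {
    rass <- p$assessments[p$assessments$kind == "RASS" &
                          p$assessments$rater == "nurse", ]
    expect_gte(nrow(rass), 3L)             # ~every 2 h over 6 h
    expect_true(all(diff(rass$time) > 3600 & diff(rass$time) < 10800))
    cam <- p$assessments[p$assessments$kind == "CAM-ICU", ]
    expect_equal(nrow(cam), 1L)            # ~daily cadence: one per 6-h stay
    expect_true(all(rass$value %in% -5:0))
  }
  coh2 <- generate_cohort(3, hours_per_patient = 6, seed = 19)
  expect_identical(coh$patients[[2]]$schedule, coh2$patients[[2]]$schedule)
  r1 <- cohort_record(coh, 1)
  r1b <- cohort_record(coh2, 1)
  expect_identical(r1$data, r1b$data)
  # different seeds give different signals (identical length by design)
  coh3 <- generate_cohort(3, hours_per_patient = 6, seed = 20)
  r3 <- cohort_record(coh3, 1)
  expect_equal(ncol(r3$data), ncol(r1$data))
  expect_gt(max(abs(r3$data - r1$data)), 1)
})

test_that("bipolar derivations of a cohort record recover the state signal", {
  coh <- generate_cohort(2, hours_per_patient = 6, seed = 23)
  rec <- cohort_record(coh, 2)
  expect_equal(rec$channel_labels, c("Fp1", "F7", "Fp2", "F8"))
  bip <- rereference(rec)
  # the schedule's first block: amplitude matches its spec scale
  lev <- as.character(coh$patients[[2]]$schedule$rass[1])
  spec <- coh$specs[[lev]]
  seg_rms <- stats::sd(bip$data[1, 1:10000])
  expect_lt(abs(seg_rms - spec$amplitude) / spec$amplitude, 0.6)
  expect_equal(cohort_true_rass(coh, 2, 10), coh$patients[[2]]$schedule$rass[1])
})
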