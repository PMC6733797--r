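test_that("eeg_record enforces its invariants", {
  expect_error(eeg_record(matrix(0, 2, 10), fs = 0, c("a", "b")), "positive")
  expect_error(eeg_record(matrix(0, 2, 10), 250, c("a", "a")), "unique")
  expect_error(eeg_record(matrix(0, 2, 10), 250, "a"), "label")
  rec <- eeg_record(matrix(rnorm(20), 2), 250, c("a", "b"))
  expect_s3_class(rec, "eeg_record")
  expect_equal(record_duration(rec), 10 / 250)
})

test_that("rereference computes the bipolar differences", {
  rec <- eeg_record(rbind(Fp1 = c(5, 5), F7 = c(2, 3),
                          Fp2 = c(0, 0), F8 = c(0, 0)),
                    250, c("Fp1", "F7", "Fp2", "F8"))
  out <- rereference(rec)
  expect_equal(out$channel_labels, c("Fp1-F7", "Fp2-F8"))
  expect_equal(out$data[1, ], c(3, 2))
  expect_equal(out$data[2, ], c(0, 0))
})

test_that("rereference cancels identical electrodes and is linear", {
  x <- matrix(rnorm(4 * 100), 4)
  x[2, ] <- x[1, ]                      # F7 == Fp1
  rec <- eeg_record(x, 250, c("Fp1", "F7", "Fp2", "F8"))
  out <- rereference(rec)
  expect_equal(max(abs(out$data[1, ])), 0)
  # linearity: rereference(a * x) = a * rereference(x)
  rec3 <- eeg_record(3.7 * x, 250, c("Fp1", "F7", "Fp2", "F8"))
  expect_equal(rereference(rec3)$data, 3.7 * out$data)
})

test_that("rereference tolerates label dialects and is idempotent on bipolar input", {
  x <- matrix(rnorm(4 * 50), 4)
  rec <- eeg_record(x, 250, c("EEG Fp1", "EEG F7", "Fp2-Ref", "f8"))
  out <- rereference(rec)
  expect_equal(out$data[1, ], x[1, ] - x[2, ])
  again <- rereference(out)
  expect_equal(again$data, out$data)
  expect_equal(again$channel_labels, out$channel_labels)
})

test_that("rereference names the missing channel", {
  rec <- eeg_record(matrix(rnorm(300), 3), 250, c("F7", "Fp2", "F8"))
  expect_error(rereference(rec), "Fp1")
})

test_that("EDF round-trip preserves data to quantization precision", {
  set.seed(5)
  rec <- eeg_record(matrix(rnorm(4 * 250 * 5, 0, 40), 4), 250,
                    c("Fp1", "F7", "Fp2", "F8"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$fs, 250)
  expect_equal(back$channel_labels, rec$channel_labels)
  # 16-bit quantization of the physical range
  span <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(back$data - rec$data)), span / 65000)
  # loading a file lacking Fp1 succeeds; downstream rereference errors
  rec3 <- eeg_record(rec$data[2:4, , drop = FALSE], 250, c("F7", "Fp2", "F8"))
  f3 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec3, f3)
  loaded <- load_recording(f3)
  expect_s3_class(loaded, "eeg_record")
  expect_error(rereference(loaded), "Fp1")
})

test_that("our EDF writer agrees with an independent reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  has_mne <- system2("python", c("-c", shQuote("import mne")),
                     stdout = FALSE, stderr = FALSE) == 0L
  skip_if_not(has_mne, "mne not importable")
  set.seed(9)
  rec <- eeg_record(matrix(rnorm(2 * 250 * 3, 0, 25), 2), 250,
                    c("Fp1-F7", "Fp2-F8"))
  f <- withr::local_tempfile(fileext = ".edf")
  out_txt <- paste0(f, ".txt")
  write_edf(rec, f)
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf('%s', preload=True, verbose='ERROR')\n",
    "np.savetxt('%s', raw.get_data() * 1e6, fmt='%%.6f')\n"), f, out_txt)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  expect_equal(system2("python", sf, stdout = FALSE, stderr = FALSE), 0L)
  ext <- as.matrix(utils::read.table(out_txt))
  # independent reader agrees with ours to well under quantization
  expect_lt(max(abs(ext - read_edf(f)$data)), 1e-4)
  span <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(ext - rec$data)), span / 32000)
})

test_that("load_recording rejects missing files and unknown formats", {
  expect_error(load_recording("no-such-file.edf"), "no such file")
  expect_error(load_recording("rec.xyz"), "format")
})

test_that("assessment tables validate values and round-trip through CSV", {
  expect_error(assessments(0, "RASS", 1), "-5..0")
  expect_error(assessments(0, "CAM-ICU", 2), "0 or 1")
  expect_error(assessments(0, "RASS", -3, rater = "doctor"), "rater")
  a <- assessments(c(10, 7200), c("RASS", "CAM-ICU"), c(-3L, 1L),
                   rater = c("nurse", "technician"), patient = 4L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_assessments(a, f)
  b <- read_assessments(f)
  expect_equal(b$time, a$time)
  expect_equal(b$value, a$value)
  expect_equal(b$rater, a$rater)
  expect_equal(b$patient, a$patient)
})
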