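test_that("read_table_recording reads mapped columns and drops NaN rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("t,emg1,angle1",
               "0,1.5,10",
               "0.005,NaN,11",
               "0.01,2.5,12"), csv)
  cmap <- list(emg1 = channel_spec("emg1", "emg"),
               angle1 = channel_spec("angle1", "angle"))
  expect_message(rec <- read_table_recording(csv, cmap, rate = 200),
                 "dropped 1 row")
  expect_equal(nrow(rec$samples), 2L)
  expect_equal(rec$dropped, 1L)
  expect_equal(colnames(rec$samples), c("emg1", "angle1"))
  expect_equal(rec$samples[, "emg1"], c(1.5, 2.5), ignore_attr = TRUE)

  # clean 3-row read-through
  writeLines(c("t,emg1,angle1", "0,1,10", "1,2,11", "2,3,12"), csv)
  rec <- read_table_recording(csv, cmap, rate = 200)
  expect_equal(nrow(rec$samples), 3L)
  expect_equal(length(rec$channels), 2L)

  expect_error(read_table_recording(tempfile(), cmap, 200), "not found")
  expect_error(read_table_recording(csv, c(cmap, list(
    missing_col = channel_spec("x", "emg"))), 200), "missing_col")
  writeLines(c("emg1,angle1", "NaN,1"), csv)
  expect_error(read_table_recording(csv, cmap, 200), "no usable rows")
})

test_that("CSV write/read round trip preserves values and channel order", {
  rec <- make_recording(n = 50, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  cmap <- stats::setNames(rec$channels, colnames(rec$samples))
  back <- read_table_recording(path, cmap, rec$rate)
  expect_equal(colnames(back$samples), colnames(rec$samples))
  expect_lt(max(abs(back$samples - rec$samples)), 1e-9)
  # bit-stable dialect: writing twice gives identical bytes
  path2 <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("decimate keeps every k-th sample from sample 0", {
  rec1k <- make_recording(n = 1000, rate = 1000)
  out <- decimate(rec1k, step_ms = 5)
  expect_equal(out$rate, 200)
  expect_equal(nrow(out$samples), 200L)
  expect_equal(out$samples, rec1k$samples[seq(1, 1000, by = 5), ])

  # unit factor is the identity
  rec200 <- make_recording(n = 100, rate = 200)
  expect_equal(decimate(rec200, 5)$samples, rec200$samples)

  # 200 Hz -> 20 Hz keeps indices 0, 10, 20, ... (brute-force enumeration)
  out20 <- decimate(rec200, 50)
  expect_equal(out20$rate, 20)
  kept <- integer(0)
  i <- 0L
  while (i < 100L) { kept <- c(kept, i + 1L); i <- i + 10L }
  expect_equal(out20$samples, rec200$samples[kept, ])

  expect_error(decimate(rec200, 7), "not an integer multiple")
})

test_that("decimate composes: factors a then b equal a single a*b", {
  rec <- make_recording(n = 600, rate = 1000)
  two_step <- decimate(decimate(rec, 2), 10)      # factor 2 then 5
  one_step <- decimate(rec, 10)                   # factor 10
  expect_equal(two_step$samples, one_step$samples)
  expect_equal(two_step$rate, one_step$rate)
})

test_that("align_bundle reconciles rates and lengths", {
  pred <- make_recording(n = 1000, rate = 1000, seed = 3)
  targ <- make_recording(n = 200, rate = 200, kinds = c("moment", "moment"),
                         seed = 4)
  b <- align_bundle(pred, targ)
  expect_true(b$aligned)
  expect_equal(b$predictors$rate, 200)
  expect_equal(nrow(b$predictors$samples), nrow(b$targets$samples))
  expect_equal(nrow(b$predictors$samples), 200L)

  # equal-rate equal-length input unchanged
  p2 <- make_recording(n = 100, rate = 200)
  t2 <- make_recording(n = 100, rate = 200, kinds = "moment")
  b2 <- align_bundle(p2, t2)
  expect_equal(b2$predictors$samples, p2$samples)
  expect_equal(b2$targets$samples, t2$samples)

  # min-length truncation
  p3 <- make_recording(n = 205, rate = 200)
  b3 <- align_bundle(p3, t2)
  expect_equal(nrow(b3$predictors$samples), 100L)

  # non-integer rate ratio refused
  p4 <- make_recording(n = 100, rate = 300)
  expect_error(align_bundle(p4, t2), "non-integer")
})

test_that("recording invariants are enforced", {
  expect_error(channel_spec("", "emg"), "nonempty")
  expect_error(channel_spec("x", "velocity"))
  expect_error(signal_recording(matrix(1, 3, 2),
                                make_channels("emg"), 200),
               "one column per channel")
  expect_error(signal_recording(matrix(1, 3, 1),
                                make_channels("emg"), 0), "positive")
})

test_that("nested subject/date/mode/sensor directories load", {
  root <- tempfile("gait_repo_mock")
  d <- file.path(root, "AB01", "2020_01_01", "treadmill", "emg")
  dir.create(d, recursive = TRUE)
  rec <- make_recording(n = 30)
  write_recording_csv(rec, file.path(d, "trial_01.csv"))
  write_recording_csv(rec, file.path(d, "trial_02.csv"))
  cmap <- stats::setNames(rec$channels, colnames(rec$samples))
  out <- read_nested_recordings(root, cmap, 200)
  expect_length(out, 2L)
  expect_equal(out[[1]]$subject_id, "AB01")
  expect_equal(out[[1]]$trial_id, "trial_01")
  expect_error(read_nested_recordings(tempfile(), cmap, 200), "not found")
})
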