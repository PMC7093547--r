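test_that("severity classes use half-open 5/15/30 intervals and are monotone", {
  expect_equal(as.character(severity_of(4.9)), "No-OSA")
  expect_equal(as.character(severity_of(5)), "mild")
  expect_equal(as.character(severity_of(14.999)), "mild")
  expect_equal(as.character(severity_of(15)), "moderate")
  expect_equal(as.character(severity_of(30)), "severe")
  expect_equal(as.character(severity_of(0)), "No-OSA")
  expect_error(severity_of(-1), "ahi")
  # monotone and total on a dense grid
  grid <- seq(0, 80, by = 0.01)
  cls <- severity_of(grid)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("chronological split takes the first floor(n * fraction) records", {
  recs <- as.list(seq_len(239))
  sp <- split_train_test(recs, 0.60)
  expect_length(sp$train, 143)
  expect_length(sp$test, 96)
  sp10 <- split_train_test(as.list(letters[1:10]), 0.60)
  expect_equal(unlist(sp10$train), letters[1:6])
  expect_equal(unlist(sp10$test), letters[7:10])
  # partition: union is the input, intersection empty, order preserved
  expect_equal(c(unlist(sp10$train), unlist(sp10$test)), letters[1:10])
  df <- data.frame(i = 1:7)
  spdf <- split_train_test(df, 0.5)
  expect_equal(spdf$train$i, 1:3)
  expect_equal(spdf$test$i, 4:7)
  expect_error(split_train_test(list(), 0.6), "empty")
})

test_that("recording CSV round-trip is lossless", {
  set.seed(42)
  rec <- recording("rt01",
                   oximetry_signal(round(runif(900, 88, 97), 1), 3),
                   airflow_signal(rnorm(1500), 5),
                   reference_ahi = 17.3)
  dir <- withr::local_tempdir()
  meta <- write_recording(rec, dir)
  back <- read_recording(meta, "csv")
  expect_equal(back$spo2$samples, rec$spo2$samples, tolerance = 1e-12)
  expect_equal(back$airflow$samples, rec$airflow$samples,
               tolerance = 1e-12)
  expect_equal(back$spo2$fs, 3)
  expect_equal(back$airflow$fs, 5)
  expect_equal(back$reference_ahi, 17.3)
  expect_equal(back$id, "rt01")
})

test_that("EDF reader recovers channels, rates and values from a byte-level fixture", {
  path <- withr::local_tempfile(fileext = ".edf")
  spo2 <- rep(c(94, 95, 96, 94.5), 10)         # 4 Hz, 10 s
  flow <- sin(2 * pi * 0.25 * seq(0, 9.875, by = 0.125))  # 8 Hz
  write_edf_fixture(path,
                    labels = c("SpO2 finger", "Nasal Pressure"),
                    fs = c(4, 8), signals = list(spo2, flow),
                    phys_min = c(0, -2), phys_max = c(100, 2))
  rec <- read_recording(path, "edf")
  expect_equal(rec$spo2$fs, 4)
  expect_equal(rec$airflow$fs, 8)
  # int16 quantisation over the declared physical range
  expect_equal(rec$spo2$samples, spo2, tolerance = 1e-3)
  expect_equal(rec$airflow$samples, flow, tolerance = 1e-4)

  # a file without an airflow-like channel is rejected with a clear error
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(path2, labels = c("SpO2", "ECG"),
                    fs = c(4, 8), signals = list(spo2, flow),
                    phys_min = c(0, -2), phys_max = c(100, 2))
  expect_error(read_recording(path2, "edf"), "no EDF channel matching")
})

test_that("feature-table round-trip preserves values and rejects unknown columns", {
  tab <- toy_feature_table(8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$spo2_ODI3, tab$spo2_ODI3, tolerance = 1e-9)
  expect_equal(back$reference_ahi, tab$reference_ahi, tolerance = 1e-9)

  bad <- tab
  names(bad)[2] <- "mystery_feature"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_feature_table(path2), "unknown feature columns")
})

test_that("the dual-channel registry defines 21 + 17 = 38 named features", {
  reg <- feature_registry()
  expect_length(reg$spo2, 21)
  expect_length(reg$airflow, 17)
  cols <- c(feature_names("spo2"), feature_names("airflow"))
  expect_length(cols, 38)
  expect_false(anyDuplicated(cols) > 0)
})

test_that("event sets enforce the 10-s floor for respiratory events", {
  expect_error(event_set("apnoea", 0, 8, 0.95), ">= 10 s")
  ev <- event_set(c("apnoea", "desaturation"), c(0, 20), c(12, 8),
                  c(0.95, 4))
  expect_equal(nrow(ev), 2)
  expect_error(event_set("breath", 0, 12, 1), "unknown event kind")
})
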