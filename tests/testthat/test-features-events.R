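scripted_spo2 <- function(dips, total_s = 3600, fs = 3, base = 95) {
  x <- rep(base, total_s * fs)
  t <- (seq_along(x) - 1) / fs
  for (d in dips) {
    sel <- t >= d$onset & t < d$onset + d$dur
    x[sel] <- base - d$depth
  }
  sig <- oximetry_signal(x, fs)
  sig$processed <- TRUE
  sig
}

test_that("scripted desaturations are counted at both 3% and 4% thresholds", {
  dips <- lapply(seq(300, 3300, length.out = 5), function(o) {
    list(onset = o, dur = 40, depth = 4.5)
  })
  sig <- scripted_spo2(dips)
  expect_equal(nrow(detect_desaturations(sig, 3)), 5)
  expect_equal(nrow(detect_desaturations(sig, 4)), 5)
})

test_that("slow drift is not a desaturation and 3.5% dips split the thresholds", {
  fs <- 3
  drift <- oximetry_signal(95 - 2 * seq(0, 1, length.out = 3600 * fs), fs)
  drift$processed <- TRUE
  expect_equal(nrow(detect_desaturations(drift, 3)), 0)

  one <- scripted_spo2(list(list(onset = 1200, dur = 60, depth = 3.5)))
  expect_equal(nrow(detect_desaturations(one, 3)), 1)
  expect_equal(nrow(detect_desaturations(one, 4)), 0)
})

test_that("nearby desaturations merge and sub-10-s dips are discarded", {
  close_pair <- scripted_spo2(list(
    list(onset = 600, dur = 20, depth = 5),
    list(onset = 625, dur = 20, depth = 5)))   # 5-s gap: merge
  expect_equal(nrow(detect_desaturations(close_pair, 3)), 1)
  brief <- scripted_spo2(list(list(onset = 600, dur = 6, depth = 5)))
  expect_equal(nrow(detect_desaturations(brief, 3)), 0)
})

test_that("oximetric indices follow their definitions", {
  fs <- 3
  const <- oximetry_signal(rep(95, 6 * 3600 * fs), fs)
  const$processed <- TRUE
  idx <- oximetric_indices(const)
  expect_equal(unname(idx), c(0, 0, 95, 95, 0))

  # 36 min below 90% out of 6 h valid -> CT90 = 10
  x <- rep(95, 6 * 3600 * fs)
  x[seq_len(36 * 60 * fs)] <- 88
  low <- oximetry_signal(x, fs)
  low$processed <- TRUE
  expect_equal(oximetric_indices(low)[["CT90"]], 10)
  expect_equal(oximetric_indices(low)[["Sat_MIN"]], 88)

  # 12 desats (4 of them >= 4%) in 4 h -> ODI3 = 3, ODI4 = 1
  dips <- lapply(seq_len(12), function(i) {
    list(onset = 1000 * i, dur = 30, depth = if (i <= 4) 5 else 3.4)
  })
  sig <- scripted_spo2(dips, total_s = 4 * 3600)
  idx2 <- oximetric_indices(sig)
  expect_equal(idx2[["ODI3"]], 3)
  expect_equal(idx2[["ODI4"]], 1)
})

test_that("ODI3 is never below ODI4", {
  for (seed in 1:5) {
    sim <- quick_sim(runif(1, 0, 50), seed = 200 + seed,
                     trt_minutes = 120)
    sp <- clean_spo2(sim$recording$spo2)$signal
    idx <- oximetric_indices(sp)
    expect_gte(idx[["ODI3"]], idx[["ODI4"]])
  }
})

test_that("airflow event detection recovers scripted amplitude drops", {
  fs <- 5
  t <- seq(0, 3600 - 1 / fs, by = 1 / fs)
  breath <- sin(2 * pi * 0.25 * t)

  sig0 <- airflow_signal(breath, fs)
  sig0$processed <- TRUE
  ev0 <- detect_airflow_events(sig0)
  expect_equal(nrow(ev0), 0)
  expect_equal(respiratory_disturbance_index(ev0, 1), 0)

  # one 15-s 95% reduction -> one apnoea
  env <- rep(1, length(t))
  env[t >= 1800 & t < 1815] <- 0.05
  sig1 <- airflow_signal(breath * env, fs)
  sig1$processed <- TRUE
  ev1 <- detect_airflow_events(sig1)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$kind, "apnoea")
  expect_lt(abs(ev1$onset_s - 1800), 5)
  expect_lt(abs(ev1$duration_s - 15), 5)

  # a 50% reduction of 20 s -> one hypopnoea
  env2 <- rep(1, length(t))
  env2[t >= 900 & t < 920] <- 0.5
  sig2 <- airflow_signal(breath * env2, fs)
  sig2$processed <- TRUE
  ev2 <- detect_airflow_events(sig2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "hypopnoea")
})

test_that("detected airflow events track the simulator truth", {
  # 20 scripted events in a 4-h night
  sleep_h <- 240 / 60 * 0.87
  target <- 20 / sleep_h
  sim <- quick_sim(target, seed = 77)
  truth_n <- sum(sim$truth_events$kind %in% c("apnoea", "hypopnoea"))
  expect_equal(truth_n, 20)
  af <- clean_airflow(sim$recording$airflow)$signal
  ev <- detect_airflow_events(af)
  expect_lte(abs(nrow(ev) - truth_n), 2)
  rdi <- respiratory_disturbance_index(ev, valid_seconds(af) / 3600)
  expect_equal(rdi, nrow(ev) / (valid_seconds(af) / 3600))
})

test_that("feature extraction yields the 38-column table and honours the registry", {
  sim <- quick_sim(30, seed = 12)
  pp <- preprocess_recording(sim$recording)
  row <- extract_features(pp$recording)
  expect_equal(ncol(row), 1 + 38 + 1)  # id + features + reference_ahi
  expect_named(row, c("id", feature_names("spo2"),
                      feature_names("airflow"), "reference_ahi"))
  expect_false(anyNA(row))
  # range invariants on this recording
  expect_true(row$spo2_SE >= 0 && row$spo2_SE <= 1)
  expect_true(row$af_SE >= 0 && row$af_SE <= 1)
  expect_true(row$spo2_WD >= 0 && row$spo2_WD <= pi / 2)
  expect_true(row$spo2_CTM >= 0 && row$spo2_CTM <= 1)
  expect_true(row$spo2_PR >= 0 && row$spo2_PR <= 1)
  expect_true(row$spo2_CT90 >= 0 && row$spo2_CT90 <= 100)

  small <- extract_features(pp$recording,
                            registry = list(spo2 = "ODI3",
                                            airflow = character()))
  expect_named(small, c("id", "spo2_ODI3", "reference_ahi"))

  raw <- quick_sim(30, seed = 12)$recording
  expect_error(extract_features(raw), "cleaned")
})

test_that("severity-linked indices separate a silent from a severe night", {
  quiet <- quick_sim(0, seed = 21)
  severe <- quick_sim(60, seed = 22)
  tab <- extract_feature_table(list(quiet, severe))
  expect_equal(nrow(tab), 2)
  expect_gt(tab$spo2_ODI3[2], tab$spo2_ODI3[1])
  expect_gt(tab$af_RDI[2], tab$af_RDI[1])
  expect_gt(tab$spo2_CT90[2], tab$spo2_CT90[1])
})
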