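# Synthetic polysomnography generator.
#
# Emulates the two channels a type-IV home monitor records: a
# quasi-periodic breathing airflow trace whose amplitude collapses during
# scripted apnoeas/hypopnoeas, and an SpO2 trace showing lagged
# desaturation dips after each respiratory event. Ground-truth events and
# AHI are returned alongside, so every downstream stage can be validated
# without clinical data.

#' Simulation configuration
#'
#' Defaults describe a typical home sleep study: 450 min total recording
#' time, 87% sleep efficiency, baseline saturation 94%, breathing at
#' 0.25 Hz, event durations with median 22.4 s truncated to \[10, 90\] s,
#' desaturations of 3-12% lagging events by 15-30 s.
#'
#' @param target_ahi Target apnoea-hypopnoea index, events per hour of
#'   simulated sleep.
#' @param trt_minutes Total recording time in minutes.
#' @param sleep_efficiency Fraction of the recording spent asleep; the
#'   ground-truth AHI divides by sleep time while downstream indices
#'   divide by valid recording time, reproducing the intrinsic
#'   underestimation of recording-time indices.
#' @param apnoea_fraction Share of respiratory events that are apnoeas
#'   (amplitude drop >= 90%); the rest are hypopnoeas (drop 30-90%).
#' @param duration_median_s,duration_sdlog Event-duration law: log-normal
#'   with this median and log-sd, rejected outside
#'   `[duration_min_s, duration_max_s]`.
#' @param duration_min_s,duration_max_s Duration bounds in seconds.
#' @param desat_lag_s Length-2 range of the lag (s) between event onset
#'   and the start of the associated desaturation.
#' @param desat_depth_pct Length-2 range of desaturation depth (%SpO2);
#'   depth grows linearly with event duration inside this range, with
#'   jitter.
#' @param baseline_spo2 Baseline saturation in %.
#' @param breath_freq_hz Respiratory frequency in Hz.
#' @param noise_sd Named numeric: Gaussian noise SD per channel
#'   (`spo2` in %, `airflow` in amplitude units).
#' @param artifact_rate Artefacts per hour injected at generation time
#'   (see [inject_artifacts()] for kinds); 0 disables.
#' @param fs_spo2,fs_airflow Sampling rates in Hz (nominal device rates
#'   75 and 250 Hz; lower rates give proportionally cheaper cohorts).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(target_ahi = 30, trt_minutes = 450,
                       sleep_efficiency = 0.87, apnoea_fraction = 0.2,
                       duration_median_s = 22.4, duration_sdlog = 0.35,
                       duration_min_s = 10, duration_max_s = 90,
                       desat_lag_s = c(15, 30),
                       desat_depth_pct = c(3, 12),
                       baseline_spo2 = 94, breath_freq_hz = 0.25,
                       noise_sd = c(spo2 = 0.15, airflow = 0.05),
                       artifact_rate = 0,
                       fs_spo2 = 75, fs_airflow = 250, seed = NULL) {
  stopifnot(target_ahi >= 0, trt_minutes > 0,
            sleep_efficiency > 0, sleep_efficiency <= 1,
            apnoea_fraction >= 0, apnoea_fraction <= 1,
            duration_min_s >= 10, duration_max_s > duration_min_s,
            length(desat_lag_s) == 2L, length(desat_depth_pct) == 2L,
            breath_freq_hz > 0, fs_spo2 > 0, fs_airflow > 0)
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Raised-cosine envelope multiplier for one event: 1 outside the event,
# `factor` over its core, ~2 s smooth ramps at the edges.
event_envelope_mult <- function(t, onset, dur, factor, ramp = 2) {
  m <- rep(1, length(t))
  ramp <- min(ramp, dur / 4)
  in_core <- t >= (onset + ramp) & t < (onset + dur - ramp)
  m[in_core] <- factor
  up <- t >= onset & t < (onset + ramp)
  m[up] <- 1 + (factor - 1) * (1 - cos(pi * (t[up] - onset) / ramp)) / 2
  dn <- t >= (onset + dur - ramp) & t < (onset + dur)
  m[dn] <- factor + (1 - factor) *
    (1 - cos(pi * (t[dn] - (onset + dur - ramp)) / ramp)) / 2
  m
}

draw_durations <- function(n, cfg) {
  if (n == 0L) return(numeric())
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, meanlog = log(cfg$duration_median_s),
                       sdlog = cfg$duration_sdlog)
    out <- c(out, d[d >= cfg$duration_min_s & d <= cfg$duration_max_s])
  }
  out[seq_len(n)]
}

#' Simulate one dual-channel recording with known ground truth
#'
#' Respiratory events are placed by a renewal process (exponential gaps
#' rescaled to fit the recording without overlap, minimum 10 s apart) so
#' that the realised event count equals `round(target_ahi * sleep_hours)`.
#' The airflow is an amplitude-modulated oscillation at the breathing
#' frequency whose envelope collapses multiplicatively during events; the
#' SpO2 trace is baseline plus slow drift minus lagged desaturation
#' pulses (linear fall over the event, exponential recovery), with
#' Gaussian noise and 0.1% quantisation.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `simulated_recording` with elements
#'   `recording` (a [recording()] whose `reference_ahi` is the true AHI),
#'   `truth_events` (an [event_set()] holding respiratory and
#'   desaturation events), and `true_ahi`
#'   (`3600 * n_events / sleep_seconds`).
#' @export
simulate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    trt_s <- cfg$trt_minutes * 60
    sleep_s <- trt_s * cfg$sleep_efficiency
    n_ev <- round(cfg$target_ahi * sleep_s / 3600)
    min_gap <- 10

    dur <- draw_durations(n_ev, cfg)
    slack <- trt_s - sum(dur) - (n_ev + 1) * min_gap
    if (slack < 0) {
      max_n <- floor((trt_s - min_gap) / (cfg$duration_median_s + min_gap))
      stop(sprintf(
        "infeasible event density: target AHI %.1f needs %d events; at most ~%.1f events/h fit in %.0f min",
        cfg$target_ahi, n_ev, max_n * 3600 / sleep_s, cfg$trt_minutes))
    }
    if (n_ev > 0) {
      w <- stats::rexp(n_ev + 1)
      gaps <- min_gap + slack * w / sum(w)
      onset <- cumsum(gaps)[seq_len(n_ev)] +
        c(0, cumsum(dur))[seq_len(n_ev)]
      kind <- ifelse(stats::runif(n_ev) < cfg$apnoea_fraction,
                     "apnoea", "hypopnoea")
      drop <- ifelse(kind == "apnoea",
                     stats::runif(n_ev, 0.90, 1.00),
                     stats::runif(n_ev, 0.30, 0.90))
    } else {
      onset <- dur <- drop <- numeric()
      kind <- character()
    }

    # airflow channel
    t_af <- seq(0, trt_s - 1 / cfg$fs_airflow, by = 1 / cfg$fs_airflow)
    env <- 1 + 0.08 * sin(2 * pi * t_af / 600) +
      0.04 * sin(2 * pi * t_af / 97)
    for (i in seq_len(n_ev)) {
      i0 <- max(1L, floor(onset[i] * cfg$fs_airflow) + 1L)
      i1 <- min(length(t_af),
                ceiling((onset[i] + dur[i]) * cfg$fs_airflow) + 1L)
      env[i0:i1] <- env[i0:i1] *
        event_envelope_mult(t_af[i0:i1], onset[i], dur[i], 1 - drop[i])
    }
    phase <- stats::runif(1, 0, 2 * pi)
    af <- env * sin(2 * pi * cfg$breath_freq_hz * t_af + phase) +
      stats::rnorm(length(t_af), sd = cfg$noise_sd[["airflow"]])

    # SpO2 channel
    t_sp <- seq(0, trt_s - 1 / cfg$fs_spo2, by = 1 / cfg$fs_spo2)
    drift_phase <- stats::runif(2, 0, 2 * pi)
    sp <- cfg$baseline_spo2 +
      0.4 * sin(2 * pi * t_sp / 5400 + drift_phase[1]) +
      0.2 * sin(2 * pi * t_sp / 1100 + drift_phase[2])
    desat <- data.frame(onset_s = numeric(), duration_s = numeric(),
                        depth = numeric())
    if (n_ev > 0) {
      lag <- stats::runif(n_ev, cfg$desat_lag_s[1], cfg$desat_lag_s[2])
      frac <- (dur - cfg$duration_min_s) /
        (cfg$duration_max_s - cfg$duration_min_s)
      depth <- cfg$desat_depth_pct[1] +
        diff(cfg$desat_depth_pct) * frac + stats::rnorm(n_ev, sd = 0.75)
      depth <- pmin(pmax(depth, cfg$desat_depth_pct[1]),
                    cfg$desat_depth_pct[2])
      tau <- 15
      for (i in seq_len(n_ev)) {
        s0 <- onset[i] + lag[i]
        if (s0 >= trt_s) next  # desat would start after lights-on
        i0 <- min(length(t_sp), max(1L, floor(s0 * cfg$fs_spo2) + 1L))
        i1 <- min(length(t_sp),
                  ceiling((s0 + dur[i] + 6 * tau) * cfg$fs_spo2) + 1L)
        idx <- i0:i1
        tt <- t_sp[idx]
        fall <- tt >= s0 & tt < s0 + dur[i]
        sp[idx][fall] <- sp[idx][fall] - depth[i] * (tt[fall] - s0) / dur[i]
        rec_t <- tt >= s0 + dur[i]
        sp[idx][rec_t] <- sp[idx][rec_t] -
          depth[i] * exp(-(tt[rec_t] - s0 - dur[i]) / tau)
      }
      desat <- data.frame(onset_s = onset + lag,
                          duration_s = dur + tau * log(pmax(depth, 1)),
                          depth = depth)
    }
    sp <- sp + stats::rnorm(length(t_sp), sd = cfg$noise_sd[["spo2"]])
    sp <- round(pmin(pmax(sp, 50), 100) * 10) / 10

    truth <- event_set(
      kind = c(kind, rep("desaturation", nrow(desat))),
      onset_s = c(onset, desat$onset_s),
      duration_s = c(dur, desat$duration_s),
      depth = c(drop, desat$depth))
    true_ahi <- 3600 * n_ev / sleep_s

    rec <- recording(
      id = sprintf("sim_ahi%04.1f", cfg$target_ahi),
      spo2 = oximetry_signal(sp, cfg$fs_spo2),
      airflow = airflow_signal(af, cfg$fs_airflow),
      reference_ahi = true_ahi, trt_seconds = trt_s)

    if (cfg$artifact_rate > 0) {
      rec <- inject_artifacts(rec, "spo2_spike", cfg$artifact_rate / 2)
      rec <- inject_artifacts(rec, "airflow_dropout", cfg$artifact_rate / 2)
    }

    structure(list(recording = rec, truth_events = truth,
                   true_ahi = true_ahi),
              class = "simulated_recording")
  })
}

#' @export
print.simulated_recording <- function(x, ...) {
  n_resp <- sum(x$truth_events$kind %in% c("apnoea", "hypopnoea"))
  cat(sprintf("<simulated recording> true AHI %.1f events/h (%d events)\n",
              x$true_ahi, n_resp))
  print(x$recording)
  invisible(x)
}

#' Simulate a cohort of recordings
#'
#' @param n Number of recordings.
#' @param ahi_law Distribution of target AHI across the cohort. Either
#'   `list(type = "severity_mixture", probs = c(...))` drawing a severity
#'   class first (default probabilities 6.3/22.6/23.4/47.7% for
#'   No-OSA/mild/moderate/severe, then AHI uniform within the class, with
#'   severe spanning 30-60 events/h), or
#'   `list(type = "uniform", range = c(lo, hi))`.
#' @param cfg Base [sim_config()]; its `target_ahi` and `seed` are
#'   overridden per recording.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @return List of [simulate_recording()] results.
#' @export
simulate_cohort <- function(n, ahi_law = list(type = "severity_mixture",
                                              probs = c(0.063, 0.226,
                                                        0.234, 0.477)),
                            cfg = sim_config(), seed = 1L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    ahi <- switch(
      ahi_law$type,
      severity_mixture = {
        stopifnot(length(ahi_law$probs) == 4L)
        cls <- sample.int(4L, n, replace = TRUE,
                          prob = ahi_law$probs / sum(ahi_law$probs))
        lo <- c(0, 5, 15, 30)[cls]
        hi <- c(5, 15, 30, 60)[cls]
        stats::runif(n, lo, hi)
      },
      uniform = stats::runif(n, ahi_law$range[1], ahi_law$range[2]),
      stop("unknown ahi_law type: ", ahi_law$type))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      ci <- cfg
      ci$target_ahi <- ahi[i]
      ci$seed <- seeds[i]
      sim <- simulate_recording(ci)
      sim$recording$id <- sprintf("sim%03d", i)
      sim
    })
  })
}

#' Inject acquisition artefacts into a recording
#'
#' `spo2_spike` inserts short (<= 2 s) excursions to saturations below
#' 50%, mimicking probe displacement; `airflow_dropout` flatlines
#' contiguous airflow segments of 30-300 s, mimicking sensor
#' malfunction.
#'
#' @param rec A [recording()].
#' @param kind `"spo2_spike"` or `"airflow_dropout"`.
#' @param rate Artefacts per hour of recording (>= 0).
#' @param seed Optional seed.
#' @return The modified recording, with the injected intervals in
#'   `attr(, "artifacts")` (data frame `kind`, `onset_s`, `duration_s`).
#' @export
inject_artifacts <- function(rec, kind = c("spo2_spike", "airflow_dropout"),
                             rate, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "recording"), rate >= 0)
  prev <- attr(rec, "artifacts")
  if (is.null(prev)) {
    prev <- data.frame(kind = character(), onset_s = numeric(),
                       duration_s = numeric())
  }
  n_art <- round(rate * rec$trt_seconds / 3600)
  if (n_art == 0L) {
    attr(rec, "artifacts") <- prev
    return(rec)
  }
  with_seed(seed, {
    if (kind == "spo2_spike") {
      sig <- rec$spo2
      dur <- stats::runif(n_art, 0.5, 2)
      onset <- stats::runif(n_art, 0, rec$trt_seconds - max(dur))
      for (i in seq_len(n_art)) {
        idx <- which(seq_along(sig$samples) / sig$fs >= onset[i] &
                     seq_along(sig$samples) / sig$fs < onset[i] + dur[i])
        sig$samples[idx] <- stats::runif(length(idx), 30, 49)
      }
      rec$spo2 <- sig
    } else {
      sig <- rec$airflow
      dur <- stats::runif(n_art, 30, 300)
      onset <- stats::runif(n_art, 0, rec$trt_seconds - max(dur))
      for (i in seq_len(n_art)) {
        idx <- which(seq_along(sig$samples) / sig$fs >= onset[i] &
                     seq_along(sig$samples) / sig$fs < onset[i] + dur[i])
        sig$samples[idx] <- 0
      }
      rec$airflow <- sig
    }
    attr(rec, "artifacts") <- rbind(prev, data.frame(
      kind = kind, onset_s = onset, duration_s = dur))
    rec
  })
}
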