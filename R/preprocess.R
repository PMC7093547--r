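# Channel conditioning.
#
# SpO2: drop physically impossible samples (< 50%), remove transient
# deeps (probe-artefact slopes), decimate to the 3 Hz analysis rate.
# Airflow: remove sustained-malfunction segments (flatline / rail
# saturation), zero-phase low-pass at 1.2 Hz, decimate to the 5 Hz
# analysis rate. Recordings with < 4 h of valid signal on either channel
# after cleaning are rejected.

# Butterworth low-pass applied forward-backward (zero phase). Cutoff and
# order per design: order 4 at 1.2 Hz for the final smoothing stage.
design_lowpass <- function(cutoff_hz, fs, order = 4) {
  signal::butter(order, cutoff_hz / (fs / 2), type = "low")
}

interp_invalid <- function(x, valid) {
  if (all(valid)) return(x)
  if (!any(valid)) stop("no valid samples")
  idx <- seq_along(x)
  x[!valid] <- stats::approx(idx[valid], x[valid], xout = idx[!valid],
                             rule = 2)$y
  x
}

# Low-pass + rate reduction: halve the rate (with a 0.45*Nyquist guard
# filter) until within a factor 4 of the target, then apply the final
# cutoff and resample onto the exact output grid.
decimate_signal <- function(x, fs, fs_out, final_cutoff_hz) {
  # filter about the mean so startup transients (zero initial state)
  # stay proportional to the fluctuation, not the DC level
  mu <- mean(x)
  x <- x - mu
  while (fs / fs_out > 4 + 1e-9) {
    ba <- signal::butter(4, 0.45, type = "low")
    x <- signal::filtfilt(ba, x)
    x <- x[seq(1, length(x), by = 2L)]
    fs <- fs / 2
  }
  ba <- design_lowpass(final_cutoff_hz, fs)
  x <- signal::filtfilt(ba, x)
  r <- fs / fs_out
  if (abs(r - round(r)) < 1e-9) {
    x <- x[seq(1, length(x), by = as.integer(round(r)))]
  } else {
    t_in <- (seq_along(x) - 1) / fs
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
    x <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  }
  x + mu
}

# Map invalid input samples onto the output grid: an output sample is
# invalid when any invalid input sample falls in its nearest-neighbour
# window.
project_mask <- function(valid_in, fs_in, n_out, fs_out) {
  out <- rep(TRUE, n_out)
  if (all(valid_in)) return(out)
  t_bad <- (which(!valid_in) - 1) / fs_in
  bins <- unique(pmin(pmax(round(t_bad * fs_out) + 1L, 1L), n_out))
  out[bins] <- FALSE
  out
}

# Transient-deep rule: 1-s-averaged SpO2 moving faster than 4 %/s in
# either direction indicates probe artefact; the interval enclosed
# between a fall and the next recovery (within `max_span_s`) is
# invalidated too.
transient_deep_mask <- function(x, fs, slope_limit = 4, max_span_s = 30) {
  w <- max(1L, as.integer(round(fs)))
  avg <- stats::filter(x, rep(1 / w, w), sides = 1)
  slope <- c(rep(0, w), diff(avg, lag = w))
  slope[is.na(slope)] <- 0
  bad <- abs(slope) > slope_limit
  falls <- which(slope < -slope_limit)
  rises <- which(slope > slope_limit)
  for (f in falls) {
    r <- rises[rises > f & rises <= f + max_span_s * fs]
    if (length(r)) bad[f:max(r[r <= f + max_span_s * fs])] <- TRUE
  }
  bad
}

#' Clean an SpO2 channel and decimate it to 3 Hz
#'
#' Invalidates samples below 50% saturation and transient deeps
#' (1-s-averaged slopes steeper than 4 %/s, plus the enclosed interval),
#' then anti-alias filters and decimates to the 3 Hz analysis rate.
#' Invalid stretches are bridged by interpolation for filtering but stay
#' flagged in the output `valid_mask` and never count towards valid
#' duration.
#'
#' @param raw An [oximetry_signal()] with `fs >= 3`.
#' @return A list with elements `signal` (3 Hz `oximetry_signal`, valid
#'   samples clamped to \[50, 100\], `processed` flag set) and `report`
#'   (removed-sample count and post-cleaning duration in hours).
#' @export
clean_spo2 <- function(raw) {
  stopifnot(inherits(raw, "oximetry_signal"))
  if (length(raw$samples) == 0L) stop("empty signal")
  if (raw$fs < 3) stop("SpO2 sampling rate must be >= 3 Hz")
  if (isTRUE(raw$processed)) {
    return(list(signal = raw,
                report = list(removed_spo2_samples = 0L,
                              post_duration_h = valid_seconds(raw) / 3600)))
  }
  x <- raw$samples
  valid <- raw$valid_mask & x >= 50 & is.finite(x)
  valid <- valid & !transient_deep_mask(x, raw$fs)
  removed <- sum(raw$valid_mask) - sum(valid)
  if (!any(valid)) stop("no valid SpO2 samples after cleaning")
  x <- interp_invalid(x, valid)
  fs_out <- 3
  if (abs(raw$fs - fs_out) < 1e-9) {
    y <- x
  } else {
    y <- decimate_signal(x, raw$fs, fs_out, final_cutoff_hz = 1.2)
  }
  mask <- project_mask(valid, raw$fs, length(y), fs_out)
  y[mask] <- pmin(pmax(y[mask], 50), 100)
  sig <- oximetry_signal(y, fs_out, t0 = raw$t0, valid_mask = mask)
  sig$processed <- TRUE
  list(signal = sig,
       report = list(removed_spo2_samples = removed,
                     post_duration_h = sum(mask) / fs_out / 3600))
}

# Sustained-malfunction rule: maximal segments of >= `min_flat_s` whose
# moving 10-s SD is below 1% of the whole-record SD (flatline), plus
# rail-saturation runs (>= 5 s pinned at the record extremes).
malfunction_mask <- function(x, fs, min_flat_s = 30, sd_frac = 0.01,
                             rail_s = 5) {
  n <- length(x)
  w <- max(2L, as.integer(round(10 * fs)))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i0 <- pmax(seq_len(n) - w %/% 2L, 0L)
  i1 <- pmin(seq_len(n) + (w - w %/% 2L), n)
  cnt <- i1 - i0
  sm <- cs[i1 + 1L] - cs[i0 + 1L]
  sm2 <- cs2[i1 + 1L] - cs2[i0 + 1L]
  mov_sd <- sqrt(pmax((sm2 - sm^2 / cnt) / (cnt - 1), 0))
  flat <- mov_sd < sd_frac * stats::sd(x)
  bad <- rep(FALSE, n)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_flat_s * fs
  for (k in which(keep)) bad[starts[k]:ends[k]] <- TRUE
  at_rail <- x >= max(x) - 1e-12 | x <= min(x) + 1e-12
  r <- rle(at_rail)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= rail_s * fs
  for (k in which(keep)) bad[starts[k]:ends[k]] <- TRUE
  bad
}

#' Clean an airflow channel
#'
#' Invalidates sustained-malfunction segments (flatlines of at least 30 s
#' whose moving 10-s SD falls below 1% of the whole-record SD, and
#' rail-saturation runs of at least 5 s), applies a zero-phase
#' fourth-order low-pass at 1.2 Hz, and decimates to the analysis rate.
#'
#' @param raw An [airflow_signal()] with `fs > 2.4` Hz.
#' @param fs_out Analysis rate in Hz (default 5; must be > 2.4 so the
#'   1.2 Hz passband is preserved).
#' @return A list with elements `signal` (cleaned `airflow_signal`) and
#'   `report` (seconds removed and post-cleaning duration in hours).
#' @export
clean_airflow <- function(raw, fs_out = 5) {
  stopifnot(inherits(raw, "airflow_signal"))
  if (length(raw$samples) == 0L) stop("empty signal")
  if (raw$fs <= 2.4) stop("airflow sampling rate must be > 2.4 Hz")
  if (isTRUE(raw$processed)) {
    return(list(signal = raw,
                report = list(removed_airflow_seconds = 0,
                              post_duration_h = valid_seconds(raw) / 3600)))
  }
  x <- raw$samples
  valid <- raw$valid_mask & is.finite(x)
  valid <- valid & !malfunction_mask(x, raw$fs)
  removed_s <- (sum(raw$valid_mask) - sum(valid)) / raw$fs
  if (!any(valid)) stop("no valid airflow samples after cleaning")
  x <- interp_invalid(x, valid)
  if (abs(raw$fs - fs_out) < 1e-9) {
    ba <- design_lowpass(1.2, raw$fs)
    mu <- mean(x)
    y <- signal::filtfilt(ba, x - mu) + mu
  } else {
    y <- decimate_signal(x, raw$fs, fs_out, final_cutoff_hz = 1.2)
  }
  mask <- project_mask(valid, raw$fs, length(y), fs_out)
  sig <- airflow_signal(y, fs_out, t0 = raw$t0, valid_mask = mask)
  sig$processed <- TRUE
  list(signal = sig,
       report = list(removed_airflow_seconds = removed_s,
                     post_duration_h = sum(mask) / fs_out / 3600))
}

#' Gate a cleaned recording on usable duration
#'
#' @param rec A [recording()] whose channels have been cleaned.
#' @param min_hours Minimum valid duration per channel (default 4 h,
#'   inclusive).
#' @return `TRUE` when both channels retain at least `min_hours` of valid
#'   signal.
#' @export
validate_duration <- function(rec, min_hours = 4) {
  stopifnot(inherits(rec, "recording"))
  valid_seconds(rec$spo2) >= min_hours * 3600 &&
    valid_seconds(rec$airflow) >= min_hours * 3600
}

#' Clean both channels of a recording and apply the duration gate
#'
#' @param rec A [recording()].
#' @return A list with elements `recording` (cleaned channels) and
#'   `report` (class `preprocess_report`: removal counts, per-channel
#'   post-cleaning durations in hours, and the `accepted` flag, true iff
#'   both channels keep >= 4 h).
#' @export
preprocess_recording <- function(rec) {
  sp <- clean_spo2(rec$spo2)
  af <- clean_airflow(rec$airflow)
  out <- rec
  out$spo2 <- sp$signal
  out$airflow <- af$signal
  report <- structure(
    list(removed_spo2_samples = sp$report$removed_spo2_samples,
         removed_airflow_seconds = af$report$removed_airflow_seconds,
         post_duration_h = c(spo2 = sp$report$post_duration_h,
                             airflow = af$report$post_duration_h),
         accepted = validate_duration(out)),
    class = "preprocess_report")
  list(recording = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "<preprocess report> %s | SpO2 %.2f h (removed %d samples) | airflow %.2f h (removed %.0f s)\n",
    if (x$accepted) "accepted" else "REJECTED (<4 h valid)",
    x$post_duration_h[["spo2"]], x$removed_spo2_samples,
    x$post_duration_h[["airflow"]], x$removed_airflow_seconds))
  invisible(x)
}
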