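# Event detection on the cleaned channels and the conventional indices
# derived from the counts. All per-hour indices divide by valid
# (post-cleaning) recording time, not sleep time, so they inherit the
# usual recording-time underestimation of abbreviated monitors.

#' Detect oxygen desaturation events
#'
#' An event opens when SpO2 falls at least `drop_pct` below the running
#' baseline (the maximum over the preceding 120 s, updated only outside
#' events) and closes on recovery to within 1% of that baseline. Events
#' must spend at least 10 s at or below the drop threshold; events
#' separated by less than 10 s are merged.
#'
#' @param spo2 A cleaned 3 Hz [oximetry_signal()].
#' @param drop_pct Desaturation depth threshold in % (3 for ODI3, 4 for
#'   ODI4).
#' @param min_dur_s Minimum time at or below threshold (default 10 s).
#' @param merge_gap_s Events closer than this are merged (default 10 s).
#' @return An [event_set()] of kind `"desaturation"`; `depth` is the
#'   baseline-to-nadir fall in %SpO2.
#' @export
detect_desaturations <- function(spo2, drop_pct = 3, min_dur_s = 10,
                                 merge_gap_s = 10) {
  stopifnot(inherits(spo2, "oximetry_signal"))
  ev <- .desat_scan(spo2$samples, spo2$fs, drop_pct, 120, 1)
  if (nrow(ev) == 0L) return(event_set())
  # merge events separated by < merge_gap_s
  keep <- list()
  cur <- ev[1, ]
  for (i in seq_len(nrow(ev))[-1]) {
    gap_s <- (ev[i, 1] - cur[2]) / spo2$fs
    if (gap_s < merge_gap_s) {
      cur[2] <- ev[i, 2]
      cur[3] <- cur[3] + ev[i, 3]
      cur[4] <- max(cur[4], ev[i, 4])
    } else {
      keep[[length(keep) + 1L]] <- cur
      cur <- ev[i, ]
    }
  }
  keep[[length(keep) + 1L]] <- cur
  ev <- do.call(rbind, keep)
  ev <- ev[ev[, 3] >= min_dur_s, , drop = FALSE]
  if (nrow(ev) == 0L) return(event_set())
  event_set(kind = rep("desaturation", nrow(ev)),
            onset_s = spo2$t0 + (ev[, 1] - 1) / spo2$fs,
            duration_s = (ev[, 2] - ev[, 1]) / spo2$fs,
            depth = ev[, 4])
}

#' Conventional oximetric indices
#'
#' @param spo2 A cleaned [oximetry_signal()].
#' @param desats3,desats4 [event_set()]s from [detect_desaturations()]
#'   at 3% and 4%; computed here when omitted.
#' @return Named vector: `ODI3` and `ODI4` (events per valid hour),
#'   `Sat_MIN` and `Sat_AVG` (%), `CT90` (% of valid time below 90%
#'   saturation).
#' @export
oximetric_indices <- function(spo2, desats3 = NULL, desats4 = NULL) {
  stopifnot(inherits(spo2, "oximetry_signal"))
  hours <- valid_seconds(spo2) / 3600
  if (hours <= 0) stop("zero valid duration")
  if (is.null(desats3)) desats3 <- detect_desaturations(spo2, 3)
  if (is.null(desats4)) desats4 <- detect_desaturations(spo2, 4)
  v <- spo2$samples[spo2$valid_mask]
  c(ODI3 = nrow(desats3) / hours,
    ODI4 = nrow(desats4) / hours,
    Sat_MIN = min(v),
    Sat_AVG = mean(v),
    CT90 = 100 * mean(v < 90))
}

# Breathing-amplitude envelope: sqrt(2) * moving RMS over `win_s`
# seconds (centered), approximating the oscillation amplitude.
airflow_envelope <- function(x, fs, win_s = 4) {
  n <- length(x)
  w <- max(2L, as.integer(round(win_s * fs)))
  cs2 <- cumsum(c(0, x^2))
  i0 <- pmax(seq_len(n) - w %/% 2L, 0L)
  i1 <- pmin(seq_len(n) + (w - w %/% 2L), n)
  sqrt(2 * (cs2[i1 + 1L] - cs2[i0 + 1L]) / (i1 - i0))
}

#' Detect apnoeas and hypopnoeas from the airflow envelope
#'
#' The breathing-amplitude envelope (moving RMS, `env_win_s` seconds) is
#' compared against a 120-s local reference (mean envelope outside
#' events, frozen while an event is ongoing). A candidate event is a run
#' with envelope below 70% of the reference; after compensating the
#' envelope-window smearing, runs of at least 10 s are kept. Runs whose
#' envelope stayed below 10% of the reference for at least 10 s are
#' apnoeas, the rest hypopnoeas.
#'
#' @param af A cleaned [airflow_signal()].
#' @param env_win_s Envelope window in seconds (default 4, one breathing
#'   cycle at 0.25 Hz).
#' @param min_dur_s Minimum event duration (default 10 s).
#' @return An [event_set()] with kinds `"apnoea"`/`"hypopnoea"`; `depth`
#'   is the fractional amplitude reduction at the nadir.
#' @export
detect_airflow_events <- function(af, env_win_s = 4, min_dur_s = 10) {
  stopifnot(inherits(af, "airflow_signal"))
  env <- airflow_envelope(af$samples, af$fs, env_win_s)
  ev <- .airflow_scan(env, af$fs, 120, 0.10, 0.70)
  if (nrow(ev) == 0L) return(event_set())
  pad <- env_win_s / 2
  onset <- (ev[, 1] - 1) / af$fs - pad
  dur <- (ev[, 2] - ev[, 1]) / af$fs + 2 * pad
  below_ap <- ev[, 3] + 2 * pad
  keep <- dur >= min_dur_s
  if (!any(keep)) return(event_set())
  kind <- ifelse(below_ap[keep] >= min_dur_s, "apnoea", "hypopnoea")
  event_set(kind = kind,
            onset_s = af$t0 + pmax(onset[keep], 0),
            duration_s = dur[keep],
            depth = pmin(ev[keep, 4], 1))
}

#' Respiratory disturbance index
#'
#' Total detected airflow events per hour of valid recording.
#'
#' @param events An [event_set()] from [detect_airflow_events()].
#' @param valid_hours Hours of valid airflow signal.
#' @return RDI in events/hour.
#' @export
respiratory_disturbance_index <- function(events, valid_hours) {
  if (valid_hours <= 0) stop("zero valid duration")
  sum(events$kind %in% c("apnoea", "hypopnoea")) / valid_hours
}
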