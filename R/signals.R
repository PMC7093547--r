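#' Construct an oximetry (SpO2) signal
#'
#' A uniformly sampled percent-saturation series. Values are percent
#' arterial oxygen saturation; after cleaning all retained samples lie in
#' \[50, 100\].
#'
#' @param samples Numeric vector of %SpO2 values.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Recording start offset in seconds.
#' @param valid_mask Logical vector of per-sample validity flags;
#'   defaults to all valid.
#' @return An object of class `oximetry_signal`.
#' @export
oximetry_signal <- function(samples, fs, t0 = 0, valid_mask = NULL) {
  new_channel_signal(samples, fs, t0, valid_mask, "oximetry_signal")
}

#' Construct an airflow signal
#'
#' A uniformly sampled nasal-prong-pressure series in arbitrary units.
#'
#' @inheritParams oximetry_signal
#' @param samples Numeric vector of airflow amplitudes (arbitrary units).
#' @return An object of class `airflow_signal`.
#' @export
airflow_signal <- function(samples, fs, t0 = 0, valid_mask = NULL) {
  new_channel_signal(samples, fs, t0, valid_mask, "airflow_signal")
}

new_channel_signal <- function(samples, fs, t0, valid_mask, class) {
  stopifnot(is.numeric(samples), length(fs) == 1L, fs > 0)
  samples <- as.numeric(samples)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(samples))
  stopifnot(length(valid_mask) == length(samples), is.logical(valid_mask))
  structure(
    list(samples = samples, fs = fs, t0 = t0,
         valid_mask = valid_mask, processed = FALSE),
    class = c(class, "channel_signal")
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  kind <- if (inherits(x, "oximetry_signal")) "SpO2" else "airflow"
  cat(sprintf("<%s signal> %d samples @ %g Hz (%.2f h), %d invalid%s\n",
              kind, length(x$samples), x$fs,
              length(x$samples) / x$fs / 3600,
              sum(!x$valid_mask),
              if (isTRUE(x$processed)) ", cleaned" else ""))
  invisible(x)
}

#' Duration covered by valid samples, in seconds
#'
#' @param sig A `channel_signal`.
#' @return Seconds of valid signal (count of valid samples / fs).
#' @export
valid_seconds <- function(sig) {
  stopifnot(inherits(sig, "channel_signal"))
  sum(sig$valid_mask) / sig$fs
}

#' Construct a two-channel recording
#'
#' Bundles one overnight SpO2 channel and one airflow channel with the
#' reference apnoea-hypopnoea index (AHI) when available.
#'
#' @param id Opaque recording identifier.
#' @param spo2 An `oximetry_signal`.
#' @param airflow An `airflow_signal`.
#' @param reference_ahi Reference AHI in events/hour, or `NA` when the
#'   recording is unlabelled.
#' @param trt_seconds Total recording time in seconds; defaults to the
#'   longer channel duration.
#' @return An object of class `recording`.
#' @export
recording <- function(id, spo2, airflow, reference_ahi = NA_real_,
                      trt_seconds = NULL) {
  stopifnot(inherits(spo2, "oximetry_signal"),
            inherits(airflow, "airflow_signal"))
  if (is.null(trt_seconds)) {
    trt_seconds <- max(length(spo2$samples) / spo2$fs,
                       length(airflow$samples) / airflow$fs)
  }
  stopifnot(trt_seconds > 0)
  if (!is.na(reference_ahi) && reference_ahi < 0) {
    stop("reference_ahi must be >= 0")
  }
  structure(
    list(id = as.character(id), spo2 = spo2, airflow = airflow,
         reference_ahi = as.numeric(reference_ahi),
         trt_seconds = trt_seconds),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> TRT %.2f h, reference AHI %s\n",
              x$id, x$trt_seconds / 3600,
              if (is.na(x$reference_ahi)) "unknown"
              else sprintf("%.1f events/h", x$reference_ahi)))
  print(x$spo2)
  print(x$airflow)
  invisible(x)
}

#' Respiratory / desaturation event set
#'
#' @param kind Character vector: `"apnoea"`, `"hypopnoea"` or
#'   `"desaturation"`.
#' @param onset_s Event onsets in seconds from the channel `t0`.
#' @param duration_s Event durations in seconds. Apnoeas and hypopnoeas
#'   must last at least 10 s.
#' @param depth Desaturation depth in %SpO2, or fractional amplitude
#'   reduction for respiratory events.
#' @return A data frame of class `event_set` with columns `kind`,
#'   `onset_s`, `duration_s`, `depth`. Intervals are half-open
#'   `[onset, onset + duration)`.
#' @export
event_set <- function(kind = character(), onset_s = numeric(),
                      duration_s = numeric(), depth = numeric()) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), c("apnoea", "hypopnoea", "desaturation"))
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "))
  resp <- kind %in% c("apnoea", "hypopnoea")
  if (any(duration_s[resp] < 10)) {
    stop("apnoea/hypopnoea events must last >= 10 s")
  }
  if (any(depth < 0)) stop("event depth must be >= 0")
  structure(
    data.frame(kind = kind, onset_s = as.numeric(onset_s),
               duration_s = as.numeric(duration_s),
               depth = as.numeric(depth)),
    class = c("event_set", "data.frame")
  )
}
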