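# The 38-feature battery: per channel, four time-domain moments, seven
# band-restricted spectral measures plus amplitude/power statistics,
# three non-linear descriptors, and the conventional clinical indices
# (SpO2: ODI3/ODI4/Sat_MIN/CT90; airflow: RDI). Default registry: 21
# oximetry + 17 airflow features.

#' Time-domain statistical moments
#'
#' Sample mean, unbiased variance, and skewness/kurtosis as standardised
#' third/fourth central moments (kurtosis is not excess: a normal series
#' gives 3). A zero-variance series yields `M3t = M4t = 0` with
#' attribute `degenerate = TRUE`.
#'
#' @param x Numeric vector with at least 2 values.
#' @return Named vector `M1t`, `M2t`, `M3t`, `M4t`.
#' @export
time_moments <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  v <- stats::var(x)
  if (v == 0) {
    out <- c(M1t = m, M2t = 0, M3t = 0, M4t = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cm <- x - m
  s2 <- mean(cm^2)  # population central moments for shape measures
  c(M1t = m, M2t = v,
    M3t = mean(cm^3) / s2^1.5,
    M4t = mean(cm^4) / s2^2)
}

#' Default OSA-related spectral bands
#'
#' 0.014-0.033 Hz for oximetry, 0.025-0.050 Hz for airflow.
#'
#' @return Named list of [spectral_band()]s.
#' @export
default_bands <- function() {
  list(spo2 = spectral_band(0.014, 0.033),
       airflow = spectral_band(0.025, 0.050))
}

#' The default feature registry
#'
#' Names (without channel prefix) of the features computed per channel:
#' 21 for SpO2 and 17 for airflow. The airflow registry omits `M1t`
#' (the mean is ~0 after high-pass-free low-pass filtering of an
#' oscillatory signal) and `Sat_AVG` is the oximetry `M1t` under another
#' name, so it is not duplicated as a column.
#'
#' @return Named list with character vectors `spo2` and `airflow`.
#' @export
feature_registry <- function() {
  core <- c("M1f", "M2f", "M3f", "M4f", "SE", "MF", "WD",
            "MA", "mA", "PR", "SampEn", "CTM", "LZC")
  list(
    spo2 = c("M1t", "M2t", "M3t", "M4t", core,
             "ODI3", "ODI4", "Sat_MIN", "CT90"),
    airflow = c("M2t", "M3t", "M4t", core, "RDI"))
}

channel_features <- function(sig, channel, band = default_bands()[[channel]],
                             sampen_epoch_s = 1200) {
  x <- sig$samples[sig$valid_mask]
  psd <- welch_psd(x, sig$fs)
  bs <- band_stats(psd, band)
  rho <- if (channel == "spo2") 1 else 0.25 * stats::sd(x)
  out <- c(time_moments(x),
           bs[c("M1f", "M2f", "M3f", "M4f")],
           SE = spectral_entropy(psd, band),
           MF = median_frequency(psd, band),
           WD = wootters_distance(psd, band),
           bs[c("MA", "mA", "PR")],
           SampEn = as.numeric(sample_entropy(x, m = 1,
                                              r = 0.25 * stats::sd(x),
                                              fs = sig$fs,
                                              epoch_s = sampen_epoch_s)),
           CTM = central_tendency_measure(x, rho),
           LZC = lempel_ziv_complexity(x))
  if (channel == "spo2") {
    out <- c(out, oximetric_indices(sig))
  } else {
    ev <- detect_airflow_events(sig)
    out <- c(out,
             RDI = respiratory_disturbance_index(ev,
                                                 valid_seconds(sig) / 3600))
  }
  out
}

#' Extract the feature vector of one cleaned recording
#'
#' @param rec A cleaned [recording()] (both channels `processed`); it
#'   must pass [validate_duration()].
#' @param registry Feature registry as from [feature_registry()];
#'   restrict it to compute a subset.
#' @param bands Named list of [spectral_band()]s per channel.
#' @return A one-row data frame: `id`, prefixed feature columns
#'   (`spo2_*`, `af_*`), and `reference_ahi`. Rows with any undefined
#'   feature are rejected with an error.
#' @export
extract_features <- function(rec, registry = feature_registry(),
                             bands = default_bands()) {
  stopifnot(inherits(rec, "recording"))
  if (!isTRUE(rec$spo2$processed) || !isTRUE(rec$airflow$processed)) {
    stop("channels must be cleaned first (see preprocess_recording)")
  }
  if (!validate_duration(rec)) {
    stop("recording rejected: < 4 h valid signal after cleaning")
  }
  vals <- list()
  if (length(registry$spo2)) {
    f <- channel_features(rec$spo2, "spo2", bands$spo2)
    vals <- c(vals, stats::setNames(as.list(f[registry$spo2]),
                                    paste0("spo2_", registry$spo2)))
  }
  if (length(registry$airflow)) {
    f <- channel_features(rec$airflow, "airflow", bands$airflow)
    vals <- c(vals, stats::setNames(as.list(f[registry$airflow]),
                                    paste0("af_", registry$airflow)))
  }
  if (any(vapply(vals, function(v) !is.finite(v), logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.finite, logical(1))]
    stop("undefined features for '", rec$id, "': ",
         paste(bad, collapse = ", "))
  }
  cbind(data.frame(id = rec$id), as.data.frame(vals),
        data.frame(reference_ahi = rec$reference_ahi))
}

#' Preprocess a cohort and build its feature table
#'
#' Runs [preprocess_recording()] and [extract_features()] over a list of
#' recordings (or simulated recordings), silently dropping recordings
#' rejected by the duration gate.
#'
#' @param recs List of [recording()]s or `simulated_recording`s.
#' @param registry,bands Passed to [extract_features()].
#' @return Data frame with one row per accepted recording.
#' @export
extract_feature_table <- function(recs, registry = feature_registry(),
                                  bands = default_bands()) {
  rows <- lapply(recs, function(r) {
    if (inherits(r, "simulated_recording")) r <- r$recording
    pp <- preprocess_recording(r)
    if (!pp$report$accepted) return(NULL)
    extract_features(pp$recording, registry, bands)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no recording passed the duration gate")
  do.call(rbind, rows)
}
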