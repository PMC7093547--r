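# Spectral analysis. The OSA-related bands are narrow (19 mHz wide for
# oximetry), so the Welch estimate zero-pads its FFT to a grid of at
# most 1 mHz.

#' Welch power spectral density estimate
#'
#' Hann-windowed segments of `seg_s` seconds with 50% overlap, each
#' mean-detrended, periodograms averaged. The FFT length is the next
#' power of two giving a frequency resolution of at most `df_max`.
#' One-sided scaling: the integral of the PSD over frequency matches the
#' signal variance (Parseval).
#'
#' @param x Numeric samples (use valid samples only).
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 512 s); signals
#'   shorter than one segment use a single full-length segment.
#' @param df_max Maximum frequency-grid spacing in Hz.
#' @return A list of class `psd_estimate` with `freqs` (Hz), `power`
#'   (units^2/Hz) and `df`.
#' @export
welch_psd <- function(x, fs, seg_s = 512, df_max = 0.001) {
  stopifnot(length(x) >= 8, fs > 0)
  nseg <- min(length(x), as.integer(round(seg_s * fs)))
  nfft <- 2^ceiling(log2(max(nseg, fs / df_max)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(c(seg, numeric(nfft - nseg)))
    p <- Mod(sp[seq_len(nfft %/% 2L + 1L)])^2
    acc <- acc + p
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  pxx <- acc * scale
  # one-sided: double everything except DC and Nyquist
  pxx[2:(length(pxx) - 1L)] <- 2 * pxx[2:(length(pxx) - 1L)]
  structure(list(freqs = (seq_along(pxx) - 1L) * fs / nfft,
                 power = pxx, df = fs / nfft),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<PSD estimate> %d bins, df = %.3g mHz, 0-%.3g Hz\n",
              length(x$freqs), x$df * 1000, max(x$freqs)))
  invisible(x)
}

#' Define a spectral band of interest
#'
#' Default OSA-related bands: 0.014-0.033 Hz for oximetry and
#' 0.025-0.050 Hz for airflow.
#'
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo < hi`.
#' @return A list of class `spectral_band`.
#' @export
spectral_band <- function(lo_hz, hi_hz) {
  stopifnot(lo_hz > 0, hi_hz > lo_hz)
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz), class = "spectral_band")
}

band_values <- function(psd, band) {
  sel <- psd$freqs >= band$lo_hz & psd$freqs <= band$hi_hz
  if (sum(sel) < 2L) stop("band outside PSD resolution")
  list(freqs = psd$freqs[sel], power = psd$power[sel], sel = sel)
}

#' Moments and amplitude statistics of the in-band spectrum
#'
#' Mean, variance (unbiased), skewness and kurtosis (standardised third
#' and fourth central moments, kurtosis not excess) of the in-band PSD
#' amplitudes, the maximum and minimum in-band amplitudes, and the
#' relative power `PR` = in-band power / total power excluding the DC
#' bin.
#'
#' @param psd A [welch_psd()] estimate.
#' @param band A [spectral_band()] (at least 8 in-band bins advised).
#' @return Named vector `M1f`, `M2f`, `M3f`, `M4f`, `MA`, `mA`, `PR`.
#' @export
band_stats <- function(psd, band) {
  bv <- band_values(psd, band)
  mom <- time_moments(bv$power)
  total <- sum(psd$power[psd$freqs > 0])
  pr <- if (total > 0) sum(bv$power[bv$freqs > 0]) / total else 0
  c(M1f = unname(mom["M1t"]), M2f = unname(mom["M2t"]),
    M3f = unname(mom["M3t"]), M4f = unname(mom["M4t"]),
    MA = max(bv$power), mA = min(bv$power), PR = pr)
}

#' Shannon spectral entropy of the in-band spectrum
#'
#' `SE = -sum(p_i log p_i) / log(N)` with `p_i` the in-band PSD
#' normalised to unit sum; ranges from 0 (single line) to 1 (flat).
#'
#' @inheritParams band_stats
#' @export
spectral_entropy <- function(psd, band) {
  p <- normalised_band_dist(psd, band)
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(normalised_band_dist(psd, band)))
}

#' Median frequency of the in-band spectrum
#'
#' Smallest in-band frequency at which cumulative in-band power reaches
#' 50% of the in-band total.
#'
#' @inheritParams band_stats
#' @export
median_frequency <- function(psd, band) {
  bv <- band_values(psd, band)
  tot <- sum(bv$power)
  if (tot <= 0) stop("zero in-band power")
  bv$freqs[which(cumsum(bv$power) >= tot / 2)[1]]
}

#' Wootters distance between the in-band spectrum and a flat spectrum
#'
#' `WD = arccos(sum(sqrt(p_i u_i)))` with `p` the normalised in-band PSD
#' and `u` uniform over the same bins; 0 for a flat band, approaching
#' pi/2 for a point mass over many bins.
#'
#' @inheritParams band_stats
#' @export
wootters_distance <- function(psd, band) {
  p <- normalised_band_dist(psd, band)
  u <- rep(1 / length(p), length(p))
  acos(min(1, sum(sqrt(p * u))))
}

normalised_band_dist <- function(psd, band) {
  bv <- band_values(psd, band)
  tot <- sum(bv$power)
  if (tot <= 0) stop("zero in-band power")
  bv$power / tot
}
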