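# Non-linear series descriptors: irregularity (sample entropy),
# variability (central tendency measure on first differences), and
# complexity (Lempel-Ziv phrase counting on the median-binarised
# series).

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev tolerance `r` and `A` counts pairs whose
#' length-`m + 1` extensions also match (self-matches excluded).
#' For overnight series the statistic is computed per `epoch_s`-second
#' epoch and the defined epoch values averaged, which keeps the O(n^2)
#' template count tractable; `epoch_s = NULL` gives the exact
#' whole-series value.
#'
#' @param x Numeric series (at least `m + 2` samples).
#' @param m Template length (default 1).
#' @param r Tolerance; default `0.25 * sd(x)`.
#' @param fs Sampling rate in Hz, needed when `epoch_s` is used.
#' @param epoch_s Epoch length in seconds (default `NULL`: whole series).
#' @return The sample entropy (>= 0), or `NaN` (with attribute
#'   `undefined = TRUE`) when no template matches exist.
#' @export
sample_entropy <- function(x, m = 1, r = 0.25 * stats::sd(x), fs = NULL,
                           epoch_s = NULL) {
  stopifnot(length(x) >= m + 2, r > 0)
  one <- function(seg) {
    if (length(seg) < m + 2) return(NA_real_)
    ab <- if (m == 1) {
      .sampen_counts_m1(seg, r)          # O(n log n) counting
    } else {
      .sampen_counts(seg, as.integer(m), r)
    }
    if (ab[2] == 0 || ab[1] == 0) return(NA_real_)
    -log(ab[1] / ab[2])
  }
  if (is.null(epoch_s)) {
    v <- one(x)
  } else {
    stopifnot(!is.null(fs))
    len <- as.integer(round(epoch_s * fs))
    starts <- seq(1L, length(x), by = len)
    vals <- vapply(starts, function(s) {
      one(x[s:min(s + len - 1L, length(x))])
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    v <- if (length(vals)) mean(vals) else NA_real_
  }
  if (is.na(v)) {
    v <- NaN
    attr(v, "undefined") <- TRUE
  }
  v
}

#' Central tendency measure
#'
#' Fraction of consecutive first-difference pairs
#' `(d_i, d_{i+1}) = (x_{i+1} - x_i, x_{i+2} - x_{i+1})` falling inside a
#' circle of radius `rho` around the origin of the second-order
#' difference plot. Values near 1 indicate low variability.
#'
#' @param x Numeric series (at least 3 samples).
#' @param rho Radius (> 0); the conventional choices are 1 %SpO2 for
#'   oximetry and `0.25 * sd(x)` for amplitude-normalised airflow.
#' @return CTM in \[0, 1\].
#' @export
central_tendency_measure <- function(x, rho) {
  stopifnot(length(x) >= 3, rho > 0)
  d <- diff(x)
  mean(sqrt(d[-length(d)]^2 + d[-1]^2) < rho)
}

#' Lempel-Ziv complexity
#'
#' Binarises the series at its median (`x > median(x)`), parses the
#' binary string into `c(n)` phrases by the LZ76 exhaustive-history
#' scheme, and normalises: `LZC = c(n) * log2(n) / n`, so random
#' sequences approach 1 and regular ones 0.
#'
#' @param x Numeric series (at least 2 samples).
#' @return Normalised complexity (>= 0).
#' @export
lempel_ziv_complexity <- function(x) {
  stopifnot(length(x) >= 2)
  bits <- as.integer(x > stats::median(x))
  n <- length(bits)
  .lz76_phrases(bits) * log2(n) / n
}
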