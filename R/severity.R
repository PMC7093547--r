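#' OSA severity class labels, in order
#' @keywords internal
severity_levels <- c("No-OSA", "mild", "moderate", "severe")

#' Classify an AHI into the four OSA severity classes
#'
#' Uses the conventional half-open intervals: No-OSA `[0, 5)`, mild
#' `[5, 15)`, moderate `[15, 30)`, severe `[30, Inf)` events/h.
#'
#' @param ahi Numeric vector of AHI values (events/hour, >= 0).
#' @return An ordered factor with levels `No-OSA < mild < moderate <
#'   severe`.
#' @examples
#' severity_of(c(4.9, 5, 15, 30))
#' @export
severity_of <- function(ahi) {
  stopifnot(is.numeric(ahi))
  if (any(is.na(ahi)) || any(ahi < 0)) stop("ahi must be >= 0 and non-missing")
  cut(ahi, breaks = c(0, 5, 15, 30, Inf), labels = severity_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Chronological train/test split
#'
#' Splits an acquisition-ordered list of recordings (or rows of a feature
#' table) into the first `floor(n * train_fraction)` records for training
#' and the remainder for testing, with no shuffling.
#'
#' @param records A list or data frame in acquisition order.
#' @param train_fraction Proportion in (0, 1); default 0.6.
#' @return A list with elements `train` and `test` of the same type as
#'   the input.
#' @export
split_train_test <- function(records, train_fraction = 0.6) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n == 0L) stop("empty input")
  n_train <- floor(n * train_fraction)
  idx <- seq_len(n_train)
  if (is.data.frame(records)) {
    list(train = records[idx, , drop = FALSE],
         test = records[-idx, , drop = FALSE])
  } else {
    list(train = records[idx], test = records[setdiff(seq_len(n), idx)])
  }
}
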