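#' Reference 4-class confusion matrices of the three screening models
#'
#' Published evaluation fixtures for an independent 96-patient test
#' group: the 4-class confusion matrices (rows = actual severity from
#' polysomnography, columns = estimated severity) of the
#' oximetry-only, airflow-only and dual-channel screening models. They
#' anchor the evaluation layer: every collapsed binary metric, kappa,
#' accuracy and triage fraction is recomputed from these counts.
#'
#' @return Named list of 4x4 integer matrices (`spo2`, `airflow`,
#'   `dual`) with severity dimnames.
#' @export
reference_confusion_matrices <- function() {
  dn <- list(actual = severity_levels, estimated = severity_levels)
  list(
    spo2 = matrix(c(1, 4, 1, 0,
                    2, 5, 8, 1,
                    0, 2, 24, 1,
                    0, 0, 5, 42),
                  nrow = 4, byrow = TRUE, dimnames = dn),
    airflow = matrix(c(4, 1, 1, 0,
                       1, 9, 6, 0,
                       1, 6, 14, 6,
                       0, 0, 15, 32),
                     nrow = 4, byrow = TRUE, dimnames = dn),
    dual = matrix(c(5, 1, 0, 0,
                    4, 6, 6, 0,
                    0, 3, 23, 1,
                    0, 0, 3, 44),
                  nrow = 4, byrow = TRUE, dimnames = dn))
}
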