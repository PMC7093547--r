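# AHI regression: epsilon-insensitive support-vector regression with a
# Gaussian RBF kernel k(a, b) = exp(-||a - b||^2 / (2 sigma^2)).
# Hyperparameters are chosen by leave-one-out cross-validation on the
# training set, maximising the intraclass correlation between actual and
# LOO-predicted AHI. Features are z-scored with training constants; the
# target stays on the raw AHI scale, and negative predictions are
# clamped to 0.

#' Hyperparameter grid for the RBF support-vector regressor
#'
#' Regularisation `C` over eight decades `10^-3 ... 10^4`; kernel width
#' `sigma` over the coarse decades `10^-2 ... 10^3` plus a refined set
#' around `10^2` (20, 50, 100, 150, 200, 250, 300, 500).
#'
#' @param C Regularisation values.
#' @param sigma_coarse,sigma_refined Kernel width values; duplicates are
#'   dropped.
#' @return Data frame with columns `C` and `sigma`, ordered by
#'   increasing `C` then `sigma` (the tie-break order used in tuning).
#' @export
hyperparameter_grid <- function(C = 10^(-3:4),
                                sigma_coarse = 10^(-2:3),
                                sigma_refined = c(20, 50, 100, 150,
                                                  200, 250, 300, 500)) {
  sigma <- sort(unique(c(sigma_coarse, sigma_refined)))
  grid <- expand.grid(sigma = sigma, C = C)[, c("C", "sigma")]
  grid[order(grid$C, grid$sigma), , drop = FALSE]
}

svm_fit <- function(x, y, hp, epsilon) {
  e1071::svm(x, y, type = "eps-regression", kernel = "radial",
             cost = hp$C, gamma = 1 / (2 * hp$sigma^2),
             epsilon = epsilon, scale = FALSE)
}

standardise_fit <- function(x) {
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  ok <- scale > 0
  list(centre = centre[ok], scale = scale[ok], keep = colnames(x)[ok],
       dropped = colnames(x)[!ok])
}

standardise_apply <- function(x, st) {
  scale(x[, st$keep, drop = FALSE], center = st$centre, scale = st$scale)
}

#' Leave-one-out hyperparameter tuning by ICC
#'
#' For every grid point, predicts each training recording from a model
#' fitted on the remaining ones and scores the grid point by the
#' intraclass correlation (absolute agreement) between actual and
#' LOO-predicted AHI. Ties resolve to the smaller `C`, then the smaller
#' `sigma`.
#'
#' @param train Feature table with a `reference_ahi` column.
#' @param selected Names of the feature columns to use.
#' @param grid Data frame from [hyperparameter_grid()].
#' @param epsilon Insensitivity-tube width on the AHI scale.
#' @return List with `hp` (row of `grid`), `icc` (best LOO ICC) and
#'   `loo_pred` (LOO predictions at the optimum).
#' @export
tune_svr <- function(train, selected, grid = hyperparameter_grid(),
                     epsilon = 0.1) {
  stopifnot(nrow(train) >= 3, all(selected %in% names(train)))
  y <- train$reference_ahi
  if (stats::sd(y) == 0) stop("degenerate target: constant reference AHI")
  x_raw <- as.matrix(train[, selected, drop = FALSE])
  grid <- unique(grid)
  n <- nrow(x_raw)
  best <- list(icc = -Inf, hp = NULL, loo = NULL)
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    loo <- numeric(n)
    for (i in seq_len(n)) {
      st <- standardise_fit(x_raw[-i, , drop = FALSE])
      if (!length(st$keep)) { loo[i] <- mean(y[-i]); next }
      xs <- standardise_apply(x_raw[-i, , drop = FALSE], st)
      fit <- svm_fit(xs, y[-i], hp, epsilon)
      xi <- standardise_apply(x_raw[i, , drop = FALSE], st)
      loo[i] <- max(0, stats::predict(fit, xi))
    }
    icc <- icc_agreement(y, loo)
    if (icc > best$icc + 1e-12) {
      best <- list(icc = icc, hp = hp, loo = loo)
    }
  }
  list(hp = best$hp, icc = best$icc, loo_pred = best$loo)
}

#' Fit an AHI screening model
#'
#' The package's central estimator: selects features (bootstrap FCBF
#' unless an explicit set is given), tunes the RBF support-vector
#' regressor by leave-one-out ICC, and refits on the whole training
#' table. Constant features are dropped with a warning at
#' standardisation.
#'
#' @param train Feature table (rows = recordings) with a
#'   `reference_ahi` column.
#' @param channel `"spo2"`, `"airflow"` or `"dual"`; restricts the
#'   candidate features to that channel's columns (prefix `spo2_` /
#'   `af_`), with `"dual"` using all.
#' @param features Optional explicit feature names, skipping selection.
#' @param grid Hyperparameter grid (see [hyperparameter_grid()]).
#' @param epsilon SVR tube width on the AHI scale (default 0.1).
#' @param B Bootstrap replicates for FCBF selection.
#' @param seed Seed for the selection bootstrap.
#' @return An object of class `screening_model`.
#' @export
screening_model <- function(train, channel = c("dual", "spo2", "airflow"),
                            features = NULL, grid = hyperparameter_grid(),
                            epsilon = 0.1, B = 1000, seed = 1L) {
  channel <- match.arg(channel)
  stopifnot("reference_ahi" %in% names(train))
  cand <- setdiff(names(train), c("id", "reference_ahi"))
  if (channel == "spo2") cand <- grep("^spo2_", cand, value = TRUE)
  if (channel == "airflow") cand <- grep("^af_", cand, value = TRUE)
  if (!length(cand)) stop("no candidate features for channel ", channel)
  selection <- NULL
  if (is.null(features)) {
    selection <- bootstrap_fcbf(train[, c(cand, "reference_ahi")],
                                B = B, seed = seed)
    features <- selection$selected
    if (!length(features)) stop("FCBF selected no features")
  }
  tuned <- tune_svr(train, features, grid, epsilon)
  x_raw <- as.matrix(train[, features, drop = FALSE])
  st <- standardise_fit(x_raw)
  if (length(st$dropped)) {
    warning("dropping constant feature(s): ",
            paste(st$dropped, collapse = ", "))
  }
  fit <- svm_fit(standardise_apply(x_raw, st), train$reference_ahi,
                 tuned$hp, epsilon)
  structure(
    list(channel = channel, selected_features = features,
         selection = selection, standardisation = st,
         hp = as.list(tuned$hp), epsilon = epsilon, svm = fit,
         training_icc = tuned$icc, n_train = nrow(train)),
    class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf(
    "<screening model> channel %s: %d features, C = %g, sigma = %g\n",
    x$channel, length(x$selected_features), x$hp$C, x$hp$sigma))
  cat(sprintf("  training LOO ICC = %.3f (n = %d)\n",
              x$training_icc, x$n_train))
  invisible(x)
}

#' @export
summary.screening_model <- function(object, ...) {
  cat(sprintf("AHI screening model (%s channel)\n", object$channel))
  cat(sprintf("  training recordings : %d\n", object$n_train))
  cat(sprintf("  features (%d)       : %s\n",
              length(object$selected_features),
              paste(object$selected_features, collapse = ", ")))
  if (!is.null(object$selection)) {
    cat(sprintf("  FCBF bootstrap      : B = %d, threshold %.1f\n",
                object$selection$B, object$selection$threshold))
  }
  cat(sprintf("  SVR                 : C = %g, sigma = %g, epsilon = %g\n",
              object$hp$C, object$hp$sigma, object$epsilon))
  cat(sprintf("  LOO training ICC    : %.3f\n", object$training_icc))
  invisible(object)
}

#' Predict the AHI for new recordings
#'
#' Standardises the selected features with the training constants,
#' evaluates the support-vector regressor, and clamps negative estimates
#' to zero (the AHI is a rate).
#'
#' @param object A [screening_model()].
#' @param newdata Feature table containing the model's selected columns.
#' @param ... Unused.
#' @return Numeric vector of estimated AHI values (events/h, >= 0).
#' @export
predict.screening_model <- function(object, newdata, ...) {
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(newdata[, object$selected_features, drop = FALSE])
  xs <- standardise_apply(x, object$standardisation)
  pmax(0, as.numeric(stats::predict(object$svm, xs)))
}

#' Actual-versus-estimated plot for a screening model
#'
#' @param x A [screening_model()].
#' @param newdata Feature table with `reference_ahi`; scatter of actual
#'   vs estimated AHI with the identity line and severity thresholds.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.screening_model <- function(x, newdata, ...) {
  est <- predict(x, newdata)
  act <- newdata$reference_ahi
  graphics::plot(act, est, xlab = "reference AHI (events/h)",
                 ylab = "estimated AHI (events/h)",
                 main = sprintf("screening model (%s)", x$channel), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(v = c(5, 15, 30), h = c(5, 15, 30),
                   col = "grey80", lty = 3)
  invisible(x)
}
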