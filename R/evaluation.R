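# Agreement and diagnostic-performance statistics: intraclass
# correlation (two-way, single-measure, absolute agreement),
# Bland-Altman limits, Mountain (folded empirical percentile) curves,
# 4-class confusion matrix with Cohen's kappa and overall accuracy,
# binary metrics at the 5/15/30 events/h cut-offs, Mann-Whitney AUC,
# percentile-bootstrap confidence intervals, Collop-style minimum LR+
# feasibility thresholds, and the avoidable-PSG triage calculator.

#' Intraclass correlation coefficient (absolute agreement)
#'
#' Two-way, single-measure, absolute-agreement ICC (ICC(A,1) in the
#' McGraw & Wong taxonomy) between two paired measurement vectors,
#' computed from the two-way ANOVA mean squares. Unlike Pearson
#' correlation it penalises systematic offsets.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @param type `"agreement"` (default, ICC(A,1)) or `"consistency"`
#'   (ICC(C,1), which ignores systematic offsets).
#' @return ICC value (<= 1).
#' @export
icc_agreement <- function(a, b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b), length(a) >= 3)
  n <- length(a)
  k <- 2
  dat <- cbind(a, b)
  if (stats::var(as.vector(dat)) == 0) stop("zero total variance")
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- (ss_tot - ss_row - ss_col) / ((n - 1) * (k - 1))
  if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

#' Bland-Altman agreement statistics
#'
#' Bias = mean difference (b - a); limits of agreement = bias +/- 1.96
#' SD of the differences (unbiased SD); width = the distance between the
#' limits.
#'
#' @param a Reference values.
#' @param b Estimated values.
#' @return List `bias`, `loa_low`, `loa_high`, `loa_width`, `sd_diff`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       loa_width = 2 * 1.96 * s, sd_diff = s)
}

#' Mountain (folded empirical percentile) curve
#'
#' Empirical percentile of each sorted difference, folded at the median:
#' percentiles above 50 are mapped to `100 - p`, so the curve peaks at
#' the median difference and its spread shows agreement.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Data frame `diff` (sorted differences) and
#'   `folded_percentile`.
#' @export
mountain_curve <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- sort(b - a)
  p <- 100 * seq_along(d) / length(d)
  data.frame(diff = d, folded_percentile = ifelse(p <= 50, p, 100 - p))
}

#' 4-class severity confusion matrix
#'
#' Rows = actual severity (from the reference AHI), columns = estimated
#' severity, using the 5/15/30 events/h thresholds on raw (unrounded)
#' AHI values.
#'
#' @param actual_ahi,estimated_ahi Paired AHI vectors.
#' @return 4x4 integer matrix with severity labels.
#' @export
confusion4 <- function(actual_ahi, estimated_ahi) {
  stopifnot(length(actual_ahi) == length(estimated_ahi),
            length(actual_ahi) >= 1)
  as.matrix(table(actual = severity_of(actual_ahi),
                  estimated = severity_of(estimated_ahi)))
}

#' Cohen's kappa of a confusion matrix
#'
#' Unweighted kappa: `(p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o` = trace/n and chance agreement `p_e` from the margins.
#'
#' @param conf Square confusion matrix (rows actual, columns estimated).
#' @return Kappa (<= 1; 1 iff the matrix is diagonal).
#' @export
cohen_kappa <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == ncol(conf), sum(conf) > 0)
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  (po - pe) / (1 - pe)
}

#' Overall accuracy of a confusion matrix, in percent
#'
#' @param conf Square confusion matrix.
#' @return `100 * trace / n`.
#' @export
acc4 <- function(conf) {
  conf <- as.matrix(conf)
  100 * sum(diag(conf)) / sum(conf)
}

#' Collapse a 4-class confusion matrix at a binary cut-off
#'
#' Merges the severity classes into negative (below the cut-off) and
#' positive (at or above); cut-offs must sit on a class boundary (5, 15
#' or 30 events/h).
#'
#' @param conf 4x4 severity confusion matrix (rows actual, columns
#'   estimated).
#' @param cutoff 5, 15 or 30 (events/h).
#' @return Named counts `TP`, `FP`, `FN`, `TN`.
#' @export
collapse_at <- function(conf, cutoff) {
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == 4, ncol(conf) == 4)
  if (!cutoff %in% c(5, 15, 30)) {
    stop("cutoff must be a severity class boundary (5, 15 or 30)")
  }
  pos <- which(c(0, 5, 15, 30) >= cutoff)  # class lower bounds
  c(TP = sum(conf[pos, pos]),
    FP = sum(conf[-pos, pos]),
    FN = sum(conf[pos, -pos]),
    TN = sum(conf[-pos, -pos]))
}

#' Binary diagnostic metrics from a 2x2 table
#'
#' Sensitivity, specificity, predictive values and accuracy in percent;
#' likelihood ratios as plain ratios. `LR+` is infinite when
#' specificity is 100% and `LR-` infinite when specificity is 0; these
#' flagged branches are returned as `Inf`/`NaN` rather than errors.
#'
#' @param t Named counts `TP`, `FP`, `FN`, `TN` (as from
#'   [collapse_at()]).
#' @return Named vector `Se`, `Sp`, `PPV`, `NPV`, `LR_plus`, `LR_minus`,
#'   `Acc`.
#' @export
binary_metrics <- function(t) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(t)), sum(t) > 0)
  se <- 100 * t[["TP"]] / (t[["TP"]] + t[["FN"]])
  sp <- 100 * t[["TN"]] / (t[["TN"]] + t[["FP"]])
  c(Se = se, Sp = sp,
    PPV = 100 * t[["TP"]] / (t[["TP"]] + t[["FP"]]),
    NPV = 100 * t[["TN"]] / (t[["TN"]] + t[["FN"]]),
    LR_plus = (se / 100) / (1 - sp / 100),
    LR_minus = (1 - se / 100) / (sp / 100),
    Acc = 100 * (t[["TP"]] + t[["TN"]]) / sum(t))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a positive case scores
#' above a negative one (ties count 1/2), which equals the trapezoidal
#' area under the empirical ROC curve swept over the continuous score.
#'
#' @param scores Continuous scores (e.g. estimated AHI).
#' @param labels Binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients (rows) with replacement and returns the empirical
#' 2.5/97.5 percentiles of the metric. If the metric is undefined
#' (non-finite) on more than 10% of resamples a warning notes that the
#' interval may be widened.
#'
#' @param data Data frame (or vector) of paired observations.
#' @param metric Function of a resampled `data` returning one number.
#' @param B Number of resamples (>= 100; default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `lo`, `hi`.
#' @export
bootstrap_ci <- function(data, metric, B = 1000, seed = 1L, conf = 0.95) {
  stopifnot(B >= 100)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- if (is.data.frame(data)) {
        tryCatch(metric(data[idx, , drop = FALSE]), error = function(e)
          NA_real_)
      } else {
        tryCatch(metric(data[idx]), error = function(e) NA_real_)
      }
      as.numeric(res)[1]
    }, numeric(1))
  })
  ok <- is.finite(vals)
  if (mean(!ok) > 0.10) {
    warning("metric undefined on >10% of resamples; CI may be widened")
  }
  q <- stats::quantile(vals[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Minimum positive likelihood ratio to reach a post-test probability
#'
#' Collop-style feasibility threshold for portable monitors:
#' `LR+ = post-odds / pre-odds`, i.e. the LR+ a test must exceed so that
#' a positive result lifts the pre-test probability (e.g. the cohort
#' prevalence) to the desired post-test probability.
#'
#' @param pretest Pre-test probability in (0, 1).
#' @param posttest Desired post-test probability (default 0.95).
#' @return Required LR+.
#' @export
required_lr_plus <- function(pretest, posttest = 0.95) {
  stopifnot(pretest > 0, pretest < 1, posttest > 0, posttest < 1)
  (posttest / (1 - posttest)) / (pretest / (1 - pretest))
}

#' Fraction of reference sleep studies avoided by a triage protocol
#'
#' Given a 4-class confusion matrix of a screening model, computes the
#' share of patients whose confirmatory study could be skipped:
#' `conservative` refers only patients with estimated mild or moderate
#' OSA (No-OSA estimates are followed up, severe estimates treated);
#' `extended` also treats estimated moderate cases, referring only
#' estimated mild.
#'
#' @param conf 4x4 confusion matrix (columns = estimated class).
#' @param protocol `"conservative"` or `"extended"`.
#' @return Avoidable fraction in percent.
#' @export
triage_fractions <- function(conf, protocol = c("conservative",
                                                "extended")) {
  protocol <- match.arg(protocol)
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == 4, ncol(conf) == 4)
  cols <- if (protocol == "conservative") c(1, 4) else c(1, 3, 4)
  100 * sum(conf[, cols]) / sum(conf)
}

#' Full diagnostic report for one or more screening models
#'
#' Aggregates, per model: agreement (ICC, Bland-Altman, Mountain curve),
#' the 4-class confusion matrix with kappa and overall accuracy, binary
#' metrics and AUC at each cut-off, avoidable-PSG fractions, and
#' percentile-bootstrap confidence intervals for the headline metrics.
#'
#' @param actual Reference AHI vector.
#' @param estimated Named list of estimated-AHI vectors (one per model).
#' @param cutoffs Binary cut-offs (default 5/15/30 events/h).
#' @param B Bootstrap replicates for the confidence intervals.
#' @param seed Seed for the bootstrap.
#' @return An object of class `diagnostic_report`.
#' @export
build_report <- function(actual, estimated, cutoffs = c(5, 15, 30),
                         B = 1000, seed = 1L) {
  if (!is.list(estimated)) estimated <- list(model = estimated)
  stopifnot(all(vapply(estimated, length, 1L) == length(actual)))
  models <- lapply(names(estimated), function(nm) {
    est <- estimated[[nm]]
    dat <- data.frame(a = actual, b = est)
    conf <- confusion4(actual, est)
    ci <- function(f) bootstrap_ci(dat, f, B = B, seed = seed)
    per_cut <- lapply(cutoffs, function(co) {
      t2 <- collapse_at(conf, co)
      bm <- binary_metrics(t2)
      both <- length(unique(actual >= co)) == 2L
      auc <- if (both) roc_auc(est, actual >= co) else NA_real_
      auc_ci <- if (both) {
        bootstrap_ci(data.frame(a = actual, b = est),
                     function(d) roc_auc(d$b, d$a >= co),
                     B = B, seed = seed)
      } else {
        c(lo = NA_real_, hi = NA_real_)
      }
      list(cutoff = co, table = t2, metrics = bm, auc = auc,
           ci = list(
             Se = ci(function(d) binary_metrics(
               collapse_at(confusion4(d$a, d$b), co))[["Se"]]),
             Sp = ci(function(d) binary_metrics(
               collapse_at(confusion4(d$a, d$b), co))[["Sp"]]),
             Acc = ci(function(d) binary_metrics(
               collapse_at(confusion4(d$a, d$b), co))[["Acc"]]),
             AUC = auc_ci))
    })
    names(per_cut) <- paste0("cutoff_", cutoffs)
    list(name = nm,
         icc = icc_agreement(actual, est),
         icc_ci = ci(function(d) icc_agreement(d$a, d$b)),
         bland_altman = bland_altman(actual, est),
         mountain = mountain_curve(actual, est),
         confusion = conf,
         kappa = cohen_kappa(conf),
         kappa_ci = ci(function(d) cohen_kappa(confusion4(d$a, d$b))),
         acc4 = acc4(conf),
         acc4_ci = ci(function(d) acc4(confusion4(d$a, d$b))),
         binary = per_cut,
         avoidable_psg = c(
           conservative = triage_fractions(conf, "conservative"),
           extended = triage_fractions(conf, "extended")))
  })
  names(models) <- names(estimated)
  structure(list(models = models, n = length(actual),
                 cutoffs = cutoffs, B = B, seed = seed),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat(sprintf("<diagnostic report> n = %d\n", x$n))
  for (m in x$models) {
    cat(sprintf(
      "  %s: ICC %.2f (%.2f-%.2f) | kappa %.2f | 4-class acc %.1f%%\n",
      m$name, m$icc, m$icc_ci[["lo"]], m$icc_ci[["hi"]], m$kappa,
      m$acc4))
    for (b in m$binary) {
      cat(sprintf(
        "    AHI >= %2d: Se %.1f%% Sp %.1f%% Acc %.1f%% AUC %.2f\n",
        b$cutoff, b$metrics[["Se"]], b$metrics[["Sp"]],
        b$metrics[["Acc"]], b$auc))
    }
    cat(sprintf(
      "    avoidable PSG: %.1f%% conservative, %.1f%% extended\n",
      m$avoidable_psg[["conservative"]], m$avoidable_psg[["extended"]]))
  }
  invisible(x)
}

#' Serialise a diagnostic report to JSON
#'
#' @param report A `diagnostic_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  strip <- lapply(report$models, function(m) {
    m$mountain <- NULL
    m$confusion <- as.data.frame.matrix(m$confusion)
    m
  })
  jsonlite::write_json(list(n = report$n, models = strip), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
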