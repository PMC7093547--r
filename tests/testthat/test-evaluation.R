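test_that("the agreement ICC matches ANOVA mean squares and penalises offsets", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_agreement(a, b), icc_anova_oracle(a, b),
               tolerance = 1e-12)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(x, x), 1)
  shifted <- x + 10
  expect_equal(cor(x, shifted), 1)
  expect_lt(icc_agreement(x, shifted), 0.2)
  # the consistency variant ignores the offset entirely
  expect_equal(icc_agreement(x, shifted, type = "consistency"), 1)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("Bland-Altman statistics match hand computation", {
  x <- c(10, 20, 30)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_width, 0)
  ba <- bland_altman(c(0, 0, 0), c(-2, 0, 2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(ba$loa_width, 7.84)
  # width recovers 2 * 1.96 * sigma on Gaussian differences
  set.seed(15)
  d <- rnorm(500, sd = 3)
  ba2 <- bland_altman(rep(0, 500), d)
  expect_equal(ba2$loa_width, 2 * 1.96 * 3, tolerance = 0.05 * 11.76)
})

test_that("the Mountain curve folds empirical percentiles at the median", {
  a <- rep(0, 101)
  b <- seq(-50, 50)
  mc <- mountain_curve(a, b)
  expect_equal(mc$diff, sort(b - a))
  expect_equal(max(mc$folded_percentile),
               mc$folded_percentile[which(mc$diff == 0)])
  direct <- 100 * seq_along(b) / length(b)
  expect_equal(mc$folded_percentile,
               ifelse(direct <= 50, direct, 100 - direct))
  dg <- mountain_curve(1:5, 1:5)
  expect_true(all(dg$diff == 0))
})

test_that("kappa and 4-class accuracy reproduce the published matrices", {
  ref <- reference_confusion_matrices()
  expect_equal(round(cohen_kappa(ref$dual), 2), 0.71)
  expect_equal(round(cohen_kappa(ref$spo2), 2), 0.61)
  expect_equal(round(cohen_kappa(ref$airflow), 2), 0.42)
  expect_equal(acc4(ref$dual), 100 * 78 / 96)  # 81.25, printed as 81.3
  expect_equal(round(acc4(ref$spo2), 1), 75.0)
  expect_equal(round(acc4(ref$airflow), 1), 61.5)
  # all three share the test-group severity margins
  for (m in ref) expect_equal(unname(rowSums(m)), c(6, 16, 27, 47))

  ident <- diag(c(10, 20, 30, 40))
  expect_equal(cohen_kappa(ident), 1)
  expect_equal(acc4(ident), 100)

  # cross-check against an independent implementation
  set.seed(16)
  cm <- matrix(sample(0:20, 16, replace = TRUE), 4)
  expect_equal(cohen_kappa(cm),
               e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
})

test_that("kappa is invariant under simultaneous class relabelling", {
  ref <- reference_confusion_matrices()$dual
  perm <- c(3, 1, 4, 2)
  expect_equal(cohen_kappa(ref[perm, perm]), cohen_kappa(ref))
  expect_equal(acc4(ref[perm, perm]), acc4(ref))
})

test_that("collapsing the dual matrix at 30 gives the published 2x2 table", {
  dual <- reference_confusion_matrices()$dual
  t30 <- collapse_at(dual, 30)
  expect_equal(t30, c(TP = 44, FP = 1, FN = 3, TN = 48))
  perfect <- diag(c(6, 16, 27, 47))
  expect_equal(unname(collapse_at(perfect, 15)[c("FP", "FN")]), c(0, 0))
  expect_error(collapse_at(dual, 20), "boundary")
})

test_that("binary metrics reproduce the published per-cutoff rows", {
  ref <- reference_confusion_matrices()
  expected <- reference_binary_expectations()
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    bm <- binary_metrics(collapse_at(ref[[e$model]], e$cutoff))
    expect_equal(round(bm[["Se"]], 1), e$Se)
    expect_equal(round(bm[["Sp"]], 1), e$Sp)
    expect_equal(round(bm[["PPV"]], 1), e$PPV)
    expect_equal(round(bm[["NPV"]], 1), e$NPV)
    expect_equal(bm[["LR_plus"]], e$LR_plus, tolerance = 0.006)
    expect_equal(round(bm[["LR_minus"]], 2), e$LR_minus)
    expect_equal(round(bm[["Acc"]], 1), e$Acc)
  }
  perfect <- binary_metrics(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unname(perfect[c("Se", "Sp", "Acc")]), c(100, 100, 100))
  expect_equal(perfect[["LR_plus"]], Inf)
})

test_that("metrics agree whether computed from vectors or the collapsed matrix", {
  set.seed(17)
  actual <- runif(80, 0, 60)
  est <- pmax(0, actual + rnorm(80, sd = 8))
  conf <- confusion4(actual, est)
  for (co in c(5, 15, 30)) {
    direct <- c(TP = sum(actual >= co & est >= co),
                FP = sum(actual < co & est >= co),
                FN = sum(actual >= co & est < co),
                TN = sum(actual < co & est < co))
    expect_equal(collapse_at(conf, co), direct)
  }
})

test_that("the AUC equals the pairwise Mann-Whitney count", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(roc_auc(scores, labels), 1)
  set.seed(18)
  for (i in 1:10) {
    s <- sample(1:20, 40, replace = TRUE)  # ties included
    l <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_oracle(s, l), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(roc_auc(s, l),
                   as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  }
  # permuted labels give chance-level AUC
  set.seed(19)
  s <- rnorm(200)
  l <- sample(rep(0:1, 100))
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.08)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the percentile bootstrap is seeded, degenerate-safe and calibrated", {
  d <- data.frame(v = rep(5, 30))
  ci <- bootstrap_ci(d, function(x) mean(x$v), B = 200, seed = 1)
  expect_equal(unname(ci), c(5, 5))
  ci_a <- bootstrap_ci(rnorm(50), mean, B = 200, seed = 9)
  set.seed(4242)  # the RNG state outside must not matter
  ci_b <- bootstrap_ci(rnorm(50), mean, B = 200, seed = 9)
  expect_false(identical(unname(ci_a), unname(ci_b)))  # different data
  x <- rnorm(50)
  expect_identical(bootstrap_ci(x, mean, B = 200, seed = 9),
                   bootstrap_ci(x, mean, B = 200, seed = 9))

  # coverage of the mean on Gaussian data (percentile intervals carry
  # the usual mild small-sample undercoverage)
  set.seed(99)
  hits <- 0
  trials <- 1000
  for (i in seq_len(trials)) {
    z <- rnorm(100, mean = 2)
    ci <- bootstrap_ci(z, mean, B = 600, seed = 100000 + i)
    if (ci[["lo"]] <= 2 && 2 <= ci[["hi"]]) hits <- hits + 1
  }
  expect_equal(100 * hits / trials, 95, tolerance = 2 / 95)
})

test_that("Collop feasibility thresholds follow from the test-set prevalences", {
  expect_equal(round(required_lr_plus(90 / 96), 1), 1.3)
  expect_equal(round(required_lr_plus(74 / 96), 1), 5.6)
  expect_equal(round(required_lr_plus(47 / 96), 1), 19.8)
  expect_equal(required_lr_plus(0.95), 1)
  # exact identity: LR+ * pre-odds = post-odds
  lr <- required_lr_plus(0.3, 0.8)
  expect_equal(lr * 0.3 / 0.7, 0.8 / 0.2)
})

test_that("triage protocols count avoidable confirmatory studies", {
  dual <- reference_confusion_matrices()$dual
  expect_equal(triage_fractions(dual, "conservative"), 100 * 54 / 96)
  expect_equal(triage_fractions(dual, "extended"), 100 * 86 / 96)
  ident <- diag(c(6, 16, 27, 47))
  expect_equal(triage_fractions(ident, "conservative"),
               100 * (6 + 47) / 96)
})

test_that("a full report is internally consistent", {
  set.seed(21)
  actual <- runif(60, 0, 60)
  perfect <- build_report(actual, list(m = actual), B = 150, seed = 2)
  pm <- perfect$models$m
  expect_equal(pm$icc, 1)
  expect_equal(pm$kappa, 1)
  expect_equal(pm$acc4, 100)
  expect_true(all(vapply(pm$binary,
                         function(b) b$metrics[["Acc"]] == 100,
                         logical(1))))

  est <- pmax(0, actual + rnorm(60, sd = 10))
  rep2 <- build_report(actual, list(m = est), B = 150, seed = 2)
  m <- rep2$models$m
  expect_gte(m$icc, m$icc_ci[["lo"]])
  expect_lte(m$icc, m$icc_ci[["hi"]])
  expect_gte(m$kappa, m$kappa_ci[["lo"]])
  expect_lte(m$kappa, m$kappa_ci[["hi"]])
  for (b in m$binary) {
    expect_gte(b$auc, b$ci$AUC[["lo"]] - 1e-12)
    expect_lte(b$auc, b$ci$AUC[["hi"]] + 1e-12)
    expect_equal(b$metrics[["Acc"]],
                 100 * (b$table[["TP"]] + b$table[["TN"]]) / 60)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep2, path)
  expect_true(jsonlite::validate(paste(readLines(path),
                                       collapse = "")))
})
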