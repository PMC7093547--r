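small_grid <- function() {
  hyperparameter_grid(C = c(1, 100), sigma_coarse = c(1, 10),
                      sigma_refined = 100)
}

test_that("the hyperparameter grid spans the documented C and sigma values", {
  grid <- hyperparameter_grid()
  expect_equal(sort(unique(grid$C)), 10^(-3:4))
  expect_length(unique(grid$sigma), 13)  # 6 coarse + 8 refined, 1 shared
  expect_equal(nrow(grid), 8 * 13)
  expect_true(any(grid$C == 1e4 & grid$sigma == 250))
  expect_true(any(grid$C == 1e4 & grid$sigma == 20))
  # duplicated rows collapse to the same tuning result
  tab <- toy_feature_table(12, seed = 2)
  g1 <- hyperparameter_grid(C = 10, sigma_coarse = c(5, 5),
                            sigma_refined = 5)
  t1 <- tune_svr(tab, c("spo2_ODI3", "af_RDI"), g1)
  t2 <- tune_svr(tab, c("spo2_ODI3", "af_RDI"),
                 data.frame(C = 10, sigma = 5))
  expect_equal(t1$icc, t2$icc)
  expect_equal(t1$hp$sigma, 5)
})

test_that("a high-capacity model near-interpolates its training targets", {
  tab <- toy_feature_table(10, seed = 3, noise = 0.5)
  m <- screening_model(tab, channel = "dual",
                       features = c("spo2_ODI3", "af_RDI"),
                       grid = data.frame(C = 1e6, sigma = 1),
                       epsilon = 0.01)
  pred <- predict(m, tab)
  expect_true(all(abs(pred - tab$reference_ahi) < 0.01 + 0.1))
})

test_that("negative raw outputs are clamped to zero", {
  set.seed(13)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  fit <- e1071::svm(x, rnorm(30, mean = -3.2, sd = 0.1),
                    type = "eps-regression", kernel = "radial",
                    gamma = 0.5, cost = 10, epsilon = 0.1, scale = FALSE)
  mock <- structure(
    list(channel = "dual", selected_features = "f",
         standardisation = list(centre = c(f = 0), scale = c(f = 1),
                                keep = "f", dropped = character()),
         hp = list(C = 10, sigma = 1), epsilon = 0.1, svm = fit,
         training_icc = NA_real_, n_train = 30),
    class = "screening_model")
  raw <- as.numeric(predict(fit, matrix(0.1, 1, 1,
                                        dimnames = list(NULL, "f"))))
  expect_lt(raw, 0)
  expect_equal(predict(mock, data.frame(f = 0.1)), 0)
})

test_that("predictions are invariant to affine rescaling of inputs", {
  tab <- toy_feature_table(30, seed = 4)
  feats <- c("spo2_ODI3", "spo2_CT90", "af_RDI")
  m1 <- screening_model(tab, features = feats,
                        grid = data.frame(C = 100, sigma = 2))
  tab2 <- tab
  tab2$spo2_ODI3 <- 10 * tab2$spo2_ODI3 + 5
  tab2$af_RDI <- -3 * tab2$af_RDI + 100
  m2 <- screening_model(tab2, features = feats,
                        grid = data.frame(C = 100, sigma = 2))
  newdata <- tab[1:10, ]
  newdata2 <- tab2[1:10, ]
  expect_equal(predict(m1, newdata), predict(m2, newdata2),
               tolerance = 1e-6)
})

test_that("constant feature columns are dropped with a warning", {
  tab <- toy_feature_table(15, seed = 5)
  tab$flat <- 7
  expect_warning(
    m <- screening_model(tab, features = c("spo2_ODI3", "flat"),
                         grid = data.frame(C = 10, sigma = 1)),
    "constant feature")
  expect_equal(m$standardisation$keep, "spo2_ODI3")
  expect_length(predict(m, tab), 15)
})

test_that("refitting with identical inputs reproduces predictions exactly", {
  tab <- toy_feature_table(20, seed = 6)
  m1 <- screening_model(tab, features = c("spo2_ODI3", "af_RDI"),
                        grid = small_grid())
  m2 <- screening_model(tab, features = c("spo2_ODI3", "af_RDI"),
                        grid = small_grid())
  expect_identical(predict(m1, tab), predict(m2, tab))
  expect_identical(m1$hp, m2$hp)
})

test_that("leave-one-out tuning never sees the held-out target", {
  set.seed(14)
  n <- 20
  tab <- data.frame(noise1 = rnorm(n), noise2 = rnorm(n),
                    reference_ahi = runif(n, 0, 60))
  # a huge-C model memorises the training rows...
  m <- screening_model(tab, features = c("noise1", "noise2"),
                       grid = data.frame(C = 1e6, sigma = 0.3),
                       epsilon = 0.01)
  fit_icc <- icc_agreement(tab$reference_ahi, predict(m, tab))
  expect_gt(fit_icc, 0.9)
  # ...yet its LOO score on pure noise stays near zero: the held-out
  # row's target was not available to the model that predicted it
  tuned <- tune_svr(tab, c("noise1", "noise2"),
                    data.frame(C = 1e6, sigma = 0.3), epsilon = 0.01)
  expect_lt(tuned$icc, 0.5)
})

test_that("informative synthetic features support accurate AHI recovery", {
  train <- toy_feature_table(60, seed = 7)
  test <- toy_feature_table(40, seed = 8)
  grid <- hyperparameter_grid(C = c(1, 10, 100, 1000),
                              sigma_coarse = c(1, 10),
                              sigma_refined = c(3, 30))
  tuned <- tune_svr(train, c("spo2_ODI3", "spo2_CT90", "af_RDI"), grid)
  expect_gt(tuned$icc, 0.8)
  m <- screening_model(train,
                       features = c("spo2_ODI3", "spo2_CT90", "af_RDI"),
                       grid = grid)
  expect_gt(icc_agreement(test$reference_ahi, predict(m, test)), 0.75)
  expect_error(predict(m, test[, c("id", "spo2_CT90", "reference_ahi")]),
               "missing feature")
})
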