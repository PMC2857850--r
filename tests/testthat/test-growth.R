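times5 <- c(0, 132, 265, 397, 530)
curve5 <- function(alpha, beta, gamma, t = times5) alpha / (1 + beta * exp(-gamma * t))

test_that("noise-free logistic series are recovered exactly", {
  y <- curve5(10, 9, 0.01)
  f <- fit_logistic(times5, y)
  expect_true(f$converged)
  expect_equal(unname(f$par), c(10, 9, 0.01), tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
  expect_identical(f$df, 2L)           # 5 points, 3 parameters
  # fitted mean at t = 0 is alpha / (1 + beta)
  expect_equal(f$fitted[1], f$par[["alpha"]] / (1 + f$par[["beta"]]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("degenerate and short series are handled explicitly", {
  expect_error(fit_logistic(c(0, 1, 2), c(1, 2, 3)), ">= 4 observations")
  expect_error(fit_logistic(c(0, 1, 1, 2), c(1, 2, 3, 4)), "strictly increasing")
  f <- fit_logistic(times5, rep(5, 5))   # constant trait: flagged boundary fit
  expect_false(f$converged)
  expect_equal(unname(f$par[["alpha"]]), 5)
})

test_that("pooled variance is total RSS over total error df", {
  fits <- lapply(1:10, function(i) {
    f <- fit_logistic(times5, curve5(10 + i, 9, 0.01))
    f$rss <- 2; f
  })
  expect_equal(pooled_variance(fits), 20 / 20)
  fits0 <- lapply(fits, function(f) { f$rss <- 0; f })
  expect_equal(pooled_variance(fits0), 0)
  expect_error(pooled_variance(list()), "no fits")
})

test_that("pooled variance estimates the true error variance", {
  set.seed(31)
  n <- 500
  tbv <- setNames(rnorm(n, 0, 5), sprintf("i%03d", 1:n))
  gp <- sim_growth_phenotypes(tbv, times5, 600, error_sd = 2)
  s1 <- growth_extrapolate(gp$phenotypes, target_time = 600)
  # chi-square spread around sigma^2 = 4 at 1000 pooled df
  expect_equal(s1$pooled_df, 1000)
  expect_lt(abs(s1$pooled_variance - 4) / 4, 0.15)
})

test_that("extrapolation standard errors propagate the pooled variance", {
  y <- curve5(100, 9, 0.008) + c(0.3, -0.4, 0.2, 0.1, -0.2)
  f <- fit_logistic(times5, y)
  p0 <- predict_growth(f, 600, pooled_var = 0)
  expect_equal(p0$se, 0)
  expect_equal(p0$var, 0)
  p1 <- predict_growth(f, 600, pooled_var = 1.3)
  p2 <- predict_growth(f, 600, pooled_var = 2.6)
  # doubling the pooled variance doubles each se^2 exactly
  expect_equal(p2$var, 2 * p1$var, tolerance = 1e-12)
  expect_equal(p1$prediction, p2$prediction)
  # noise-free: prediction at an observed time equals the observation
  f0 <- fit_logistic(times5, curve5(100, 9, 0.008))
  expect_equal(predict_growth(f0, 397, 1)$prediction, curve5(100, 9, 0.008)[4],
               tolerance = 1e-6)
})

test_that("the two-pass procedure runs on a population and keeps point estimates", {
  set.seed(32)
  tbv <- setNames(rnorm(40, 0, 5), sprintf("i%02d", 1:40))
  gp <- sim_growth_phenotypes(tbv, times5, 600, error_sd = 1)
  s1 <- growth_extrapolate(gp$phenotypes, target_time = 600)
  expect_equal(nrow(s1$table), 40)
  expect_equal(s1$pooled_df, 80)
  expect_equal(s1$table$var, s1$table$se^2, tolerance = 1e-12)
  # pass 2 (fixed pooled variance) does not move the least-squares optimum:
  # predictions equal the pass-1 curve values at the target time
  pass1 <- vapply(s1$fits, function(f)
    f$par[["alpha"]] / (1 + f$par[["beta"]] * exp(-f$par[["gamma"]] * 600)), 0)
  expect_equal(unname(pass1[s1$table$individual]), s1$table$prediction,
               tolerance = 1e-12)
  # single noise-free individual: exact curve value, zero residual
  one <- gp$truth[1, ]
  exact <- sim_growth_phenotypes(setNames(0, "solo"), times5, 600, error_sd = 0)
  s1s <- growth_extrapolate(exact$phenotypes, target_time = 600)
  expect_equal(s1s$table$prediction, exact$truth$value_at_target, tolerance = 1e-4)
  expect_equal(s1s$pooled_variance, 0, tolerance = 1e-10)
  expect_equal(s1s$table$se, 0, tolerance = 1e-6)
})

test_that("extrapolated logistic predictions stay below the fitted asymptote", {
  set.seed(33)
  tbv <- setNames(rnorm(30, 0, 5), sprintf("i%02d", 1:30))
  gp <- sim_growth_phenotypes(tbv, times5, 600, error_sd = 1)
  s1 <- growth_extrapolate(gp$phenotypes, target_time = 600)
  alphas <- vapply(s1$fits, function(f) f$par[["alpha"]], 0)
  ymax <- vapply(s1$fits, function(f) max(f$y), 0)
  expect_true(all(s1$table$prediction <=
                    pmax(alphas[s1$table$individual], ymax[s1$table$individual]) + 1e-8))
})
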