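test_that("shrinkage measures satisfy their definitions and edge cases", {
  b <- c(1, -2, 0.5)
  expect_equal(shrinkage(b, b), list(AS = 0, RS = 0))
  expect_equal(shrinkage(b, rep(0, 3)), list(AS = sum(b^2), RS = 1))
  expect_error(shrinkage(rep(0, 3), b), "zero norm")
  expect_error(shrinkage(b, b[1:2]), "equal length")
})

test_that("shrinkage is nonnegative and monotone along the ridge path", {
  fx <- make_test_dataset(n = 30, p = 5, rho = 0.9, seed = 71)
  cf <- canonical_transform(standardize(fx$dataset))
  ols <- fit_ridge(cf, 0)
  as_path <- vapply(c(0.01, 0.1, 1, 10), function(k)
    shrinkage(ols$beta_scaled, fit_ridge(cf, k)$beta_scaled)$AS, numeric(1))
  expect_true(all(as_path > 0))
  expect_true(all(diff(as_path) > 0))
})

test_that("coverage is scale-free in the noise and saturates for wide intervals", {
  # in-sample coverage depends only on standardized residuals, so a
  # near-noiseless fit behaves like any other correctly specified one
  fx <- make_test_dataset(n = 40, p = 3, sigma = 1e-8, seed = 72)
  s <- standardize(fx$dataset)
  cf <- canonical_transform(s)
  expect_gte(cppi(fit_ridge(cf, 0), s), 95)
  # and tightening alpha widens the intervals to full coverage
  expect_equal(cppi(fit_ridge(cf, 0), s, alpha_level = 1e-6), 100)
})

test_that("OLS prediction intervals attain nominal in-sample coverage", {
  set.seed(73)
  cov_pct <- replicate(60, {
    X <- MASS::mvrnorm(200, rep(0, 4), equicorrelated_sigma(4, 0.5))
    y <- drop(X %*% rep(0.5, 4)) + rnorm(200)
    s <- standardize(ridge_dataset(X, y))
    cppi(fit_ridge(canonical_transform(s), 0), s, alpha_level = 0.05)
  })
  expect_equal(mean(cov_pct), 95, tolerance = 0.01)
})

test_that("coverage is invariant under affine response rescaling", {
  fx <- make_test_dataset(n = 50, p = 4, rho = 0.7, seed = 74)
  d <- fx$dataset
  s1 <- standardize(d)
  c1 <- cppi(fit_ridge(canonical_transform(s1), 0.5), s1)
  d2 <- ridge_dataset(d$predictors, 10 * d$response - 3)
  s2 <- standardize(d2)
  c2 <- cppi(fit_ridge(canonical_transform(s2), 0.5), s2)
  expect_equal(c1, c2)
})

test_that("dataset evaluation ties together penalties, MSE and shrinkage", {
  fx <- make_test_dataset(n = 40, p = 4, rho = 0.9, sigma = 2, seed = 75)
  cf <- canonical_transform(standardize(fx$dataset))

  only_ols <- evaluate_dataset(fx$dataset, methods = "OLS")
  expect_equal(only_ols$table$emse_plugin,
               cf$sigma2_hat * sum(1 / cf$lambdas), tolerance = 1e-10)
  expect_equal(only_ols$table$AS, 0)
  expect_equal(only_ols$table$RS, 0)

  rep <- evaluate_dataset(fx$dataset)
  expect_setequal(rep$table$method, penalty_methods())
  expect_true(!is.unsorted(rep$table$emse_plugin))
  inp <- penalty_inputs(cf)
  for (i in seq_len(nrow(rep$table))) {
    m <- rep$table$method[i]
    expect_equal(rep$table$k[i], ridge_k(m, inp)$k, tolerance = 1e-12)
    expect_equal(rep$table$emse_plugin[i],
                 mse_theoretical(cf, rep$table$k[i]), tolerance = 1e-12)
  }
  expect_true(all(rep$table$AS[rep$table$k > 0] > 0))
  expect_true(all(rep$table$cppi >= 0 & rep$table$cppi <= 100))
})

test_that("plug-in MSE ranking of scale-invariant rules survives y-rescaling", {
  fx <- make_test_dataset(n = 40, p = 4, rho = 0.85, seed = 76)
  inv <- c("OLS", "HK", "HKB", "LW", "HSL", "KAM", "KGM", "KMED", "KAG",
           "NEW1", "NEW2")
  r1 <- evaluate_dataset(fx$dataset, methods = inv)
  d2 <- ridge_dataset(fx$dataset$predictors, 5 * fx$dataset$response)
  r2 <- evaluate_dataset(d2, methods = inv)
  expect_identical(r1$table$method, r2$table$method)
})
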