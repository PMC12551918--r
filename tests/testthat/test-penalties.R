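test_that("closed-form special cases evaluate exactly", {
  # SCI: p(1 + 1/p) sigma2 = (p+1) sigma2
  inp <- penalty_inputs(sigma2 = 1.5, alpha = rep(1, 4),
                        lambdas = rep(1, 4), n = 20, p = 4)
  expect_equal(ridge_k("SCI", inp)$k, 7.5)

  # HK: sigma2 / max alpha^2
  inp2 <- penalty_inputs(sigma2 = 2, alpha = c(0.5, 2),
                         lambdas = c(1.5, 0.5), n = 10, p = 2)
  expect_equal(ridge_k("HK", inp2)$k, 0.5)

  # KS with unit plug-ins: 1/(1+1)
  inp3 <- penalty_inputs(sigma2 = 1, alpha = c(1, 1),
                         lambdas = c(1, 1), n = 3, p = 2)
  expect_equal(ridge_k("KS", inp3)$k, 0.5)

  # mean, geometric mean and median coincide when all alpha_i^2 are equal
  inp4 <- penalty_inputs(sigma2 = 2, alpha = c(0.7, -0.7, 0.7),
                         lambdas = c(1.6, 0.9, 0.5), n = 15, p = 3)
  ks <- vapply(c("HKB", "KAM", "KGM", "KMED"),
               function(m) ridge_k(m, inp4)$k, numeric(1))
  expect_equal(max(ks) - min(ks), 0, tolerance = 1e-12)

  # LW reduces to HKB under unit eigenvalues
  inp5 <- penalty_inputs(sigma2 = 1.2, alpha = c(0.4, 1.1, -0.6),
                         lambdas = rep(1, 3), n = 12, p = 3)
  expect_equal(ridge_k("LW", inp5)$k, ridge_k("HKB", inp5)$k,
               tolerance = 1e-14)
})

test_that("all thirteen nonzero rules match the frozen symbolic oracle", {
  # expected values computed by exact rational/symbolic evaluation of the
  # formulas on this fixture, frozen here
  expected <- c(
    HK   = 2.34375,
    HKB  = 5.8823529411764705882,
    LW   = 3.2379924446842957366,
    HSL  = 1.8278580933356127620,
    KAM  = 15.627604166666666667,
    KGM  = 9.6824583655185422130,
    KMED = 11.333333333333333333,
    KS   = 0.146484375,
    KMS  = 3.2552083333333333333,
    KAG  = 2.9411764705882352941,
    SCI  = 7.5,
    NEW1 = 80.661228140060975957,
    NEW2 = 207.97258270192574247)
  inp <- oracle_inputs()
  for (m in names(expected))
    expect_equal(ridge_k(m, inp)$k, unname(expected[m]), tolerance = 1e-12,
                 label = paste("k for", m))
  expect_identical(ridge_k("OLS", inp)$k, 0)
})

test_that("condition-number-adaptive rules obey their structural identities", {
  n <- 20; p <- 4
  kag <- function(inp) ridge_k("KAG", inp)$k
  # lambda_min = lambda_max: both collapse to n * KAG
  flat <- penalty_inputs(sigma2 = 1, alpha = c(0.5, 1, -0.7, 0.2),
                         lambdas = rep(1.0, p), n = n, p = p)
  expect_equal(ridge_k("NEW1", flat)$k, n * kag(flat), tolerance = 1e-12)
  expect_equal(ridge_k("NEW2", flat)$k, n * kag(flat), tolerance = 1e-12)

  # p = 1: the exponents 1/(2p) and 1/2 coincide
  one <- penalty_inputs(sigma2 = 1, alpha = 0.8, lambdas = 2, n = 10, p = 1)
  expect_equal(ridge_k("NEW1", one)$k, ridge_k("NEW2", one)$k,
               tolerance = 1e-14)

  # default orientation: NEW2 > NEW1 > n * KAG whenever r > 1, p > 1
  inp <- oracle_inputs()
  expect_gt(ridge_k("NEW2", inp)$k, ridge_k("NEW1", inp)$k)
  expect_gt(ridge_k("NEW1", inp)$k, inp$n * kag(inp))

  # NEW2 / (n * KAG) is exactly the condition number sqrt(lmax/lmin)
  expect_equal(ridge_k("NEW2", inp)$k / (inp$n * kag(inp)),
               sqrt(max(inp$lambdas) / min(inp$lambdas)), tolerance = 1e-12)

  # the literal eigen-ratio variant inverts the ordering
  expect_lt(ridge_k("NEW2", inp, literal_ratio = TRUE)$k,
            ridge_k("NEW1", inp, literal_ratio = TRUE)$k)

  # strictly increasing in the condition ratio at fixed lambda_max
  ks2 <- vapply(c(1.5, 3, 10, 40), function(r) {
    ridge_k("NEW2", penalty_inputs(sigma2 = 1, alpha = c(1, 1),
                                   lambdas = c(2, 2 / r), n = 10, p = 2))$k
  }, numeric(1))
  expect_true(all(diff(ks2) > 0))
})

test_that("every rule is finite and nonnegative on random canonical fits", {
  for (seed in 1:8) {
    fx <- make_test_dataset(n = 20 + 5 * seed, p = 2 + seed %% 4,
                            rho = 0.3 + 0.08 * seed, seed = 100 + seed)
    tab <- all_penalties(canonical_transform(standardize(fx$dataset)))
    expect_equal(nrow(tab), 14)
    expect_true(all(is.finite(tab$k)))
    expect_true(all(tab$k >= 0))
  }
})

test_that("response rescaling leaves the scale-invariant rules unchanged", {
  fx <- make_test_dataset(n = 30, p = 4, rho = 0.8, seed = 41)
  d <- fx$dataset
  c_ <- 3.7
  d2 <- ridge_dataset(d$predictors, c_ * d$response)
  inp1 <- penalty_inputs(canonical_transform(standardize(d)))
  inp2 <- penalty_inputs(canonical_transform(standardize(d2)))
  invariant <- c("HK", "HKB", "LW", "HSL", "KAM", "KGM", "KMED", "KAG",
                 "KS", "NEW1", "NEW2")
  for (m in invariant)
    expect_equal(ridge_k(m, inp2)$k, ridge_k(m, inp1)$k, tolerance = 1e-8,
                 label = paste("scale invariance of", m))
  expect_equal(ridge_k("SCI", inp2)$k, c_^2 * ridge_k("SCI", inp1)$k,
               tolerance = 1e-8)
  expect_equal(ridge_k("KMS", inp2)$k, ridge_k("KMS", inp1)$k / c_,
               tolerance = 1e-8)
})

test_that("unknown methods and degenerate coefficients are rejected", {
  inp <- oracle_inputs()
  expect_error(ridge_k("RIDGEMAX", inp), "registry")
  bad <- penalty_inputs(sigma2 = 1, alpha = c(1, 0), lambdas = c(2, 1),
                        n = 10, p = 2)
  expect_error(ridge_k("KGM", bad), "degenerate canonical coefficient")
  expect_error(all_penalties(canonical_transform(standardize(
    make_test_dataset(seed = 42)$dataset)), methods = c("OLS", "XX")),
    "unknown method")
})
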