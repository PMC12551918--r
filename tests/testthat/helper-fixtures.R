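# Shared generators for test fixtures.  Everything is built in code from a
# fixed seed; no binary data.

make_test_dataset <- function(n = 30, p = 4, rho = 0.5, sigma = 1,
                              seed = 1, beta = NULL) {
  set.seed(seed)
  X <- MASS::mvrnorm(n, rep(0, p), equicorrelated_sigma(p, rho))
  if (is.null(beta)) beta <- seq_len(p) / sqrt(sum(seq_len(p)^2))
  y <- 2 + drop(X %*% beta) + rnorm(n, 0, sigma)
  list(dataset = ridge_dataset(X, y), beta = beta, intercept = 2)
}

# frozen canonical summaries for the penalty-formula oracle
oracle_inputs <- function() {
  penalty_inputs(sigma2 = 1.5, alpha = c(0.8, -0.5, 0.3, -0.2),
                 lambdas = c(2.5, 0.8, 0.5, 0.2), n = 20, p = 4)
}
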