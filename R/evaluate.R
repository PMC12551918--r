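#' Absolute and relative shrinkage of a ridge fit
#'
#' Quantifies how much a ridge rule contracts the coefficient vector
#' relative to OLS, on the standardized-coefficient scale:
#' \deqn{AS = \|\hat\beta_{OLS}\|^2 - \|\hat\beta_{Ridge}\|^2, \quad
#'       RS = AS / \|\hat\beta_{OLS}\|^2.}
#' Because the standardized coefficients are an orthogonal rotation of the
#' canonical coefficients and ridge contracts every canonical coordinate,
#' `AS >= 0` for any `k > 0`.
#'
#' @param beta_ols,beta_ridge coefficient vectors of equal length
#'   (standardized scale).
#' @return Named list with components `AS` and `RS`.
#' @export
shrinkage <- function(beta_ols, beta_ridge) {
  if (length(beta_ols) != length(beta_ridge))
    stop("coefficient vectors must have equal length")
  n2 <- sum(beta_ols^2)
  if (n2 <= 0) stop("OLS coefficient vector has zero norm")
  AS <- n2 - sum(beta_ridge^2)
  list(AS = AS, RS = AS / n2)
}

#' Coverage percentage of prediction intervals
#'
#' For each of the `n` fitting observations, forms the prediction interval
#' \deqn{\hat y_j \pm t_{\alpha/2,\,n-p}
#'       \sqrt{\hat\sigma^2 (1 + x_j^{*\prime}(X^{*\prime}X^*)^{-1}x_j^*)}}
#' and returns `100 *` the fraction of observed responses falling inside.
#' The leverage term always uses the unpenalized cross-product inverse of
#' the standardized design; \eqn{\hat y_j} and \eqn{\hat\sigma^2} come from
#' the supplied fit (its own residual variance by default, see `sigma2`).
#'
#' @param fit a [fit_ridge()] result.
#' @param design the [standardize()] result the fit was computed from.
#' @param alpha_level significance level of the intervals (default 0.05,
#'   i.e. nominal 95\% intervals).
#' @param sigma2 residual variance to use in the interval width; defaults
#'   to the fit's own.
#' @return Coverage percentage in `[0, 100]`.
#' @export
cppi <- function(fit, design, alpha_level = 0.05, sigma2 = fit$sigma2_hat) {
  stopifnot(inherits(fit, "ridge_fit"), inherits(design, "standardized_design"))
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must lie in (0, 1)")
  Xstar <- design$Xstar
  n <- nrow(Xstar)
  p <- ncol(Xstar)
  if (n <= p) stop("need n > p")
  XtXinv <- solve(crossprod(Xstar))
  lev <- rowSums((Xstar %*% XtXinv) * Xstar)
  half <- stats::qt(1 - alpha_level / 2, df = n - p) *
    sqrt(sigma2 * (1 + lev))
  y <- design$y_centered + design$y_mean
  inside <- y > fit$fitted - half & y < fit$fitted + half
  100 * mean(inside)
}

#' Evaluate the full penalty catalog on one dataset
#'
#' The single-pipeline real-data comparison: standardize, transform to
#' canonical form, then for each requested rule compute its ridge constant,
#' fit, and report the plug-in MSE ([mse_theoretical()] at that `k`),
#' absolute/relative shrinkage versus OLS, and prediction-interval
#' coverage.  Rows are sorted by plug-in MSE, so the preferred rule for the
#' dataset is first.
#'
#' @param dataset a [ridge_dataset()].
#' @param methods methods to evaluate (default: the full registry).
#' @param alpha_level prediction-interval significance level.
#' @param pi_sigma `"method"` (default) uses each fit's own residual
#'   variance inside the interval width; `"ols"` uses the OLS residual
#'   variance for every method.
#' @param literal_ratio passed to [ridge_k()].
#' @return An object of class `evaluation_report`: list with `table` (a
#'   data frame with columns `method`, `k`, `emse_plugin`, `AS`, `RS`,
#'   `cppi`, sorted by `emse_plugin`), `coefficients` (standardized
#'   coefficients, one column per method), `intercepts`, and the
#'   underlying `canonical` fit.
#' @examples
#' set.seed(1)
#' X <- MASS::mvrnorm(40, rep(0, 4), equicorrelated_sigma(4, 0.9))
#' y <- drop(X %*% rep(0.5, 4)) + rnorm(40)
#' evaluate_dataset(ridge_dataset(X, y))$table
#' @export
evaluate_dataset <- function(dataset, methods = penalty_methods(),
                             alpha_level = 0.05,
                             pi_sigma = c("method", "ols"),
                             literal_ratio = FALSE) {
  pi_sigma <- match.arg(pi_sigma)
  stopifnot(inherits(dataset, "ridge_dataset"))
  design <- standardize(dataset)
  canonical <- canonical_transform(design)
  bad <- setdiff(methods, penalty_methods())
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  inputs <- penalty_inputs(canonical)
  ols_fit <- fit_ridge(canonical, 0)
  rows <- lapply(methods, function(m) {
    k <- ridge_k(m, inputs, literal_ratio)$k
    fit <- fit_ridge(canonical, k)
    sh <- shrinkage(ols_fit$beta_scaled, fit$beta_scaled)
    s2 <- if (pi_sigma == "ols") ols_fit$sigma2_hat else fit$sigma2_hat
    list(row = data.frame(
      method = m, k = k,
      emse_plugin = mse_theoretical(canonical, k),
      AS = sh$AS, RS = sh$RS,
      cppi = cppi(fit, design, alpha_level, sigma2 = s2),
      stringsAsFactors = FALSE),
      beta = fit$beta_scaled, intercept = fit$intercept)
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  coefs <- do.call(cbind, lapply(rows, `[[`, "beta"))
  dimnames(coefs) <- list(dataset$column_names, methods)
  intercepts <- stats::setNames(vapply(rows, `[[`, numeric(1), "intercept"),
                                methods)
  ord <- order(tab$emse_plugin)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, coefficients = coefs,
                 intercepts = intercepts, canonical = canonical),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("Penalty-catalog evaluation (sorted by plug-in MSE):\n")
  tab <- x$table
  tab$k <- signif(tab$k, digits)
  tab$emse_plugin <- signif(tab$emse_plugin, digits)
  tab$AS <- round(tab$AS, 3)
  tab$RS <- round(tab$RS, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
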