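#' Fit a ridge (or OLS) regression at a given penalty
#'
#' Computes the ridge solution in canonical coordinates,
#' \eqn{\hat\alpha_i(k) = \lambda_i/(\lambda_i + k)\,\hat\alpha_i},
#' rotates it back to the standardized-coefficient scale
#' (\eqn{\hat\beta_{scaled} = E \hat\alpha(k)}), undoes the column scaling
#' to recover slopes in original predictor units, and reconstructs the
#' intercept \eqn{\hat\beta_0 = \bar y - \sum_j \hat\beta_j \bar x_j}.
#' With `k = 0` the fit is exactly ordinary least squares.
#'
#' @param canonical a [canonical_transform()] result.
#' @param k nonnegative ridge constant.
#' @return An object of class `ridge_fit` with components `k`,
#'   `alpha_ridge`, `beta_scaled`, `beta_original`, `intercept`, `fitted`,
#'   `residuals` (both on the original response scale) and `sigma2_hat`
#'   (this fit's residual variance with `n - p` degrees of freedom).
#' @examples
#' d <- ridge_dataset(matrix(rnorm(80), 20, 4), rnorm(20))
#' cf <- canonical_transform(standardize(d))
#' fit_ridge(cf, k = 0.5)
#' @export
fit_ridge <- function(canonical, k) {
  stopifnot(inherits(canonical, "canonical_fit"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0)
    stop("'k' must be a single nonnegative number")
  design <- canonical$design
  l <- canonical$lambdas
  alpha_k <- l / (l + k) * canonical$alpha_ols
  beta_scaled <- drop(canonical$E %*% alpha_k)
  beta_original <- beta_scaled / design$column_scales
  intercept <- design$y_mean - sum(beta_original * design$column_means)
  # fitted values on the original response scale via the standardized design
  fitted <- design$y_mean + drop(design$Xstar %*% beta_scaled)
  y <- design$y_centered + design$y_mean
  resid <- y - fitted
  structure(list(
    k = k,
    alpha_ridge = alpha_k,
    beta_scaled = beta_scaled,
    beta_original = beta_original,
    intercept = intercept,
    fitted = fitted,
    residuals = resid,
    sigma2_hat = sum(resid^2) / canonical$df_resid,
    df_resid = canonical$df_resid,
    column_names = design$column_names
  ), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, digits = 4, ...) {
  cat("ridge_fit: k =", format(x$k), "\n")
  coefs <- c("(Intercept)" = x$intercept,
             stats::setNames(x$beta_original, x$column_names))
  print(round(coefs, digits))
  cat("residual variance (df =", x$df_resid, "):", signif(x$sigma2_hat, 6), "\n")
  invisible(x)
}

#' @export
coef.ridge_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$beta_original, object$column_names))
}
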