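#' Canonical-form transformation of a standardized design
#'
#' Reparametrizes the centered/scaled linear model through the
#' eigendecomposition of the standardized cross-product matrix
#' \eqn{X^{*\prime} X^*}: with \eqn{E} orthogonal and
#' \eqn{\Lambda = \mathrm{diag}(\lambda_1 \ge \dots \ge \lambda_p)},
#' the rotated design \eqn{Z = X^* E} satisfies
#' \eqn{Z'Z = \Lambda}, so ordinary least squares decouples into
#' \eqn{\hat\alpha_i = (Z'y)_i / \lambda_i} and every ridge solution is a
#' per-coordinate contraction of \eqn{\hat\alpha}.
#'
#' The residual variance \eqn{\hat\sigma^2} is the OLS residual sum of
#' squares on the centered response divided by \eqn{n - p}; it is the
#' variance estimate used inside all penalty formulas.
#'
#' Eigenvector sign convention: the largest-magnitude entry of each column
#' of `E` is made positive, so canonical coefficients are reproducible
#' across platforms.
#'
#' @param design a [standardize()] result.
#' @param tol relative eigenvalue threshold: `lambda_min/lambda_max` below
#'   this triggers a "singular design" error rather than a silent
#'   pseudo-inverse.
#' @return An object of class `canonical_fit` with components `E`,
#'   `lambdas`, `Z`, `alpha_ols`, `sigma2_hat`, `df_resid`, plus the
#'   embedded `design`.
#' @export
canonical_transform <- function(design, tol = 1e-12) {
  stopifnot(inherits(design, "standardized_design"))
  Xstar <- design$Xstar
  n <- nrow(Xstar)
  p <- ncol(Xstar)
  S <- crossprod(Xstar)
  eig <- eigen(S, symmetric = TRUE)
  lambdas <- eig$values
  E <- eig$vectors
  if (min(lambdas) / max(lambdas) < tol || min(lambdas) <= 0)
    stop("singular design: smallest eigenvalue ratio ",
         format(min(lambdas) / max(lambdas)), " below tolerance ", tol)
  # fix sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(p)) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  Z <- Xstar %*% E
  zty <- drop(crossprod(Z, design$y_centered))
  alpha_ols <- zty / lambdas
  resid <- design$y_centered - drop(Z %*% alpha_ols)
  df <- n - p
  structure(list(
    E = E,
    lambdas = lambdas,
    Z = Z,
    alpha_ols = alpha_ols,
    sigma2_hat = sum(resid^2) / df,
    df_resid = df,
    n = n,
    p = p,
    design = design
  ), class = "canonical_fit")
}

#' @export
print.canonical_fit <- function(x, ...) {
  cat("canonical_fit: p =", x$p, ", n =", x$n, "\n")
  cat("eigenvalues:", paste(signif(x$lambdas, 4), collapse = ", "), "\n")
  cat("sigma2_hat:", signif(x$sigma2_hat, 6), " (df =", x$df_resid, ")\n")
  invisible(x)
}

#' Theoretical mean squared error of the canonical ridge estimator
#'
#' Evaluates the plug-in MSE of the ridge estimator in canonical
#' coordinates,
#' \deqn{\hat\sigma^2 \sum_i \lambda_i/(\lambda_i+k)^2 +
#'       k^2 \sum_i \hat\alpha_i^2/(\lambda_i+k)^2,}
#' the sum of the variance and squared-bias terms.  At `k = 0` this reduces
#' to the OLS value \eqn{\hat\sigma^2 \sum_i 1/\lambda_i}; as
#' `k` grows without bound it tends to the pure squared bias
#' \eqn{\sum_i \hat\alpha_i^2}.
#'
#' @param canonical a [canonical_transform()] result.
#' @param k nonnegative ridge constant.
#' @return The plug-in MSE (nonnegative scalar).
#' @export
mse_theoretical <- function(canonical, k) {
  stopifnot(inherits(canonical, "canonical_fit"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0)
    stop("'k' must be a single nonnegative number")
  l <- canonical$lambdas
  a <- canonical$alpha_ols
  canonical$sigma2_hat * sum(l / (l + k)^2) + k^2 * sum(a^2 / (l + k)^2)
}
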