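#' Collinearity diagnostics from a correlation matrix
#'
#' Variance inflation factors, condition number and the Farrar-Glauber
#' chi-square statistic, all computed from the sample correlation matrix of
#' the predictors — the scale on which multicollinearity is conventionally
#' judged.
#'
#' @name diagnostics
NULL

check_correlation <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || !isSymmetric(unname(R), tol = 1e-8))
    stop("not a valid correlation matrix: must be square and symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("not a valid correlation matrix: diagonal must be 1")
  if (any(abs(R) > 1 + 1e-8))
    stop("not a valid correlation matrix: entries must lie in [-1, 1]")
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("not a valid correlation matrix: not positive definite")
  list(R = (R + t(R)) / 2, eigenvalues = ev)
}

#' @rdname diagnostics
#' @param correlation symmetric positive-definite matrix with unit
#'   diagonal (a predictor correlation matrix).
#' @return `vif()`: the diagonal of the inverse correlation matrix — the
#'   factor by which each coefficient's variance is inflated relative to an
#'   orthogonal design.
#' @examples
#' R <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
#' vif(R)               # both 1/(1 - 0.8^2)
#' condition_number(R)  # sqrt(1.8/0.2) = 3
#' @export
vif <- function(correlation) {
  chk <- check_correlation(correlation)
  v <- diag(solve(chk$R))
  if (!is.null(colnames(correlation))) names(v) <- colnames(correlation)
  v
}

#' @rdname diagnostics
#' @return `condition_number()`: \eqn{\sqrt{\lambda_{max}/\lambda_{min}}}
#'   of the correlation matrix (equivalently, the ratio of extreme singular
#'   values of the standardized design); 1 for orthogonal predictors.
#' @export
condition_number <- function(correlation) {
  chk <- check_correlation(correlation)
  ev <- chk$eigenvalues
  sqrt(max(ev) / min(ev))
}

#' @rdname diagnostics
#' @param n number of observations behind the correlation matrix.
#' @param p number of predictors (defaults to `ncol(correlation)`).
#' @return `farrar_glauber()`: the chi-square statistic
#'   \eqn{-(n - 1 - (2p+5)/6)\,\log\det R}, large under strong
#'   collinearity and 0 for an identity correlation matrix.  The
#'   log-determinant is accumulated from the eigenvalues for numerical
#'   stability.
#' @export
farrar_glauber <- function(correlation, n, p = ncol(as.matrix(correlation))) {
  chk <- check_correlation(correlation)
  if (p != ncol(chk$R))
    stop("'p' does not match the matrix dimension")
  mult <- n - 1 - (2 * p + 5) / 6
  if (mult <= 0)
    stop("n too small for Farrar-Glauber: need n > 1 + (2p+5)/6")
  -mult * sum(log(chk$eigenvalues))
}

#' Full collinearity diagnostics report
#'
#' Computes the correlation matrix (when given a dataset), VIFs, condition
#' number and Farrar-Glauber statistic in one pass.
#'
#' @param x a [ridge_dataset()], a numeric predictor matrix, or a
#'   correlation matrix (detected by unit diagonal and symmetry; supply
#'   `n` explicitly in that case).
#' @param n number of observations; required when `x` is already a
#'   correlation matrix.
#' @return An object of class `diagnostics_report`: list with
#'   `correlation`, `vifs`, `condition_number`, `farrar_glauber`, `n`, `p`.
#' @examples
#' R <- bodyfat_cor()
#' rep <- collin_diagnostics(R, n = 50)
#' rep$condition_number
#' @export
collin_diagnostics <- function(x, n = NULL) {
  if (inherits(x, "ridge_dataset")) {
    R <- stats::cor(x$predictors)
    n <- nrow(x$predictors)
  } else {
    M <- as.matrix(x)
    is_cor <- nrow(M) == ncol(M) && isSymmetric(unname(M), tol = 1e-8) &&
      all(abs(diag(M) - 1) < 1e-8)
    if (is_cor) {
      if (is.null(n)) stop("'n' is required when 'x' is a correlation matrix")
      R <- M
    } else {
      R <- stats::cor(M)
      n <- nrow(M)
    }
  }
  p <- ncol(R)
  structure(list(
    correlation = R,
    vifs = vif(R),
    condition_number = condition_number(R),
    farrar_glauber = farrar_glauber(R, n = n, p = p),
    n = as.integer(n),
    p = as.integer(p)
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, digits = 2, ...) {
  cat("Collinearity diagnostics (n =", x$n, ", p =", x$p, ")\n")
  cat("  condition number :", round(x$condition_number, digits), "\n")
  cat("  Farrar-Glauber   :", round(x$farrar_glauber, digits), "\n")
  cat("  VIF              :", paste(round(x$vifs, digits), collapse = ", "), "\n")
  invisible(x)
}
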