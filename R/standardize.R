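#' Center and scale a dataset for canonical-form ridge regression
#'
#' Centers each predictor column and scales it to unit Euclidean norm, so
#' that the cross-product matrix of the standardized design equals the
#' sample correlation matrix of the predictors.  The response is centered
#' but not scaled.  All centering/scaling bookkeeping is retained so that
#' coefficients can be mapped back to the original units exactly.
#'
#' The Euclidean-norm convention (rather than unit standard deviation) is
#' used throughout: it is the scaling under which eigenvalues of the
#' cross-product matrix sum to `p` and condition numbers and variance
#' inflation factors read directly off the correlation matrix.
#'
#' @param dataset a [ridge_dataset()].
#' @return An object of class `standardized_design` with components:
#'   \describe{
#'     \item{Xstar}{n x p matrix, columns centered with unit Euclidean norm.}
#'     \item{y_centered}{response minus its mean.}
#'     \item{column_means, column_scales}{per-column center and Euclidean
#'       norm of the centered column (equal to `sd * sqrt(n-1)`).}
#'     \item{y_mean}{mean of the response.}
#'   }
#' @examples
#' d <- ridge_dataset(matrix(rnorm(60), 20, 3), rnorm(20))
#' s <- standardize(d)
#' round(crossprod(s$Xstar) - cor(d$predictors), 12)
#' @export
standardize <- function(dataset) {
  if (!inherits(dataset, "ridge_dataset"))
    dataset <- ridge_dataset(dataset$predictors, dataset$response)
  X <- dataset$predictors
  y <- dataset$response
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, `-`)
  scl <- sqrt(colSums(Xc^2))
  if (any(scl <= 0))
    stop("constant predictor column(s): ",
         paste(dataset$column_names[scl <= 0], collapse = ", "))
  Xstar <- sweep(Xc, 2, scl, `/`)
  structure(list(
    Xstar = Xstar,
    y_centered = y - mean(y),
    column_means = mu,
    column_scales = scl,
    y_mean = mean(y),
    column_names = dataset$column_names
  ), class = "standardized_design")
}

#' @export
print.standardized_design <- function(x, ...) {
  cat("standardized_design: n =", nrow(x$Xstar), ", p =", ncol(x$Xstar),
      "(columns centered, unit Euclidean norm)\n")
  invisible(x)
}
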