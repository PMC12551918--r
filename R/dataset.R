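#' Construct a regression dataset
#'
#' Bundles a numeric predictor matrix and a response vector, validating the
#' invariants every downstream routine relies on: more observations than
#' predictors, no missing values, and strictly positive variance in every
#' predictor column.
#'
#' @param predictors numeric matrix (or data frame coercible to one) with
#'   `n` rows and `p` columns, `n > p >= 1`.
#' @param response numeric vector of length `n`.
#' @param column_names optional character vector of predictor names;
#'   defaults to the matrix column names or `X1..Xp`.
#' @return An object of class `ridge_dataset` with components `predictors`,
#'   `response` and `column_names`.
#' @examples
#' d <- ridge_dataset(matrix(rnorm(40), 20, 2), rnorm(20))
#' d$column_names
#' @export
ridge_dataset <- function(predictors, response, column_names = NULL) {
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(column_names)) {
    column_names <- colnames(X)
    if (is.null(column_names)) column_names <- paste0("X", seq_len(p))
  }
  if (length(column_names) != p)
    stop("'column_names' must have one entry per predictor column")
  if (length(y) != n)
    stop("length of 'response' (", length(y), ") does not match nrow(predictors) (", n, ")")
  if (anyNA(X) || anyNA(y))
    stop("missing values are not allowed")
  if (n <= p)
    stop("underdetermined: need n > p, got n = ", n, ", p = ", p)
  v <- apply(X, 2, stats::var)
  if (any(v <= 0)) {
    bad <- column_names[v <= 0]
    stop("constant predictor column(s): ", paste(bad, collapse = ", "))
  }
  colnames(X) <- column_names
  structure(list(predictors = X, response = y, column_names = column_names),
            class = "ridge_dataset")
}

#' Read a regression dataset from a CSV file
#'
#' Reads a CSV file with a header row, takes the named column as the
#' response, and treats all remaining columns as numeric predictors.  Rows
#' containing any non-numeric cell are rejected with their row index.
#'
#' @param path path to a CSV file with a header row.
#' @param response name of the response column.
#' @return A [ridge_dataset()].
#' @export
read_dataset <- function(path, response) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df))
    stop("response column '", response, "' not found; columns: ",
         paste(names(df), collapse = ", "))
  num <- lapply(df, function(col) suppressWarnings(as.numeric(as.character(col))))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad) > 0)
    stop("non-numeric cell(s) in row(s): ", paste(bad, collapse = ", "))
  df <- as.data.frame(num, check.names = FALSE)
  y <- df[[response]]
  X <- as.matrix(df[setdiff(names(df), response)])
  ridge_dataset(X, y)
}

#' @export
print.ridge_dataset <- function(x, ...) {
  cat("ridge_dataset: n =", nrow(x$predictors), "observations, p =",
      ncol(x$predictors), "predictors\n")
  cat("predictors:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}
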