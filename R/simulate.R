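#' Equicorrelated correlation matrix
#'
#' Unit-diagonal matrix with a common pairwise correlation `rho`; the
#' covariance used to generate collinear Gaussian designs.  Its spectrum is
#' \eqn{1 + (p-1)\rho} (once) and \eqn{1 - \rho} (p-1 times), so it is
#' positive definite exactly when \eqn{-1/(p-1) < \rho < 1}.
#'
#' @param p number of predictors.
#' @param rho common pairwise correlation.
#' @return p x p correlation matrix.
#' @export
equicorrelated_sigma <- function(p, rho) {
  if (p < 1) stop("p must be positive")
  if (p > 1 && (rho <= -1 / (p - 1) || rho >= 1))
    stop("rho = ", rho, " outside (-1/(p-1), 1): matrix not positive definite")
  S <- matrix(rho, p, p)
  diag(S) <- 1
  S
}

#' Construct a unit-norm coefficient vector
#'
#' The simulation scheme fixes the true slope vector to squared norm 1
#' (with zero intercept), so the estimated MSE of competing estimators is
#' comparable across scenarios.  Two conventions for its direction:
#' `equal` puts equal weight \eqn{1/\sqrt p} on every predictor;
#' `eigvec_max` uses the unit eigenvector of the design correlation matrix
#' belonging to its largest eigenvalue (the classic worst-case-variance
#' direction), with sign fixed so the entries sum positive.  On an
#' equicorrelated design with `rho > 0` the two coincide.
#'
#' @param rule `"equal"` or `"eigvec_max"`.
#' @param p number of predictors.
#' @param design for `eigvec_max`: either an n x p data matrix (its
#'   correlation matrix is used) or a p x p correlation matrix.
#' @return Numeric vector of length `p` with unit Euclidean norm.
#' @export
make_beta <- function(rule, p, design = NULL) {
  rule <- match.arg(rule, c("equal", "eigvec_max"))
  if (rule == "equal") return(rep(1 / sqrt(p), p))
  if (is.null(design)) stop("rule 'eigvec_max' requires a design matrix")
  M <- as.matrix(design)
  R <- if (nrow(M) == ncol(M) && all(abs(diag(M) - 1) < 1e-8) &&
           isSymmetric(unname(M), tol = 1e-8)) M else stats::cor(M)
  v <- eigen(R, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Specify one Monte Carlo scenario
#'
#' @param rho common pairwise predictor correlation in `[0, 1)`.
#' @param p number of predictors.
#' @param sigma error standard deviation.
#' @param n sample size (must exceed `p`).
#' @param N number of Monte Carlo replications.
#' @param seed RNG seed for this scenario.
#' @param beta_rule direction convention for the unit-norm true slope
#'   vector; see [make_beta()].
#' @param redraw_X if `FALSE` (default) the design is drawn once and held
#'   fixed while only the errors are redrawn; if `TRUE` a fresh design is
#'   drawn each replication.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(rho, p, sigma, n, N = 10000, seed = 1,
                          beta_rule = c("equal", "eigvec_max"),
                          redraw_X = FALSE) {
  beta_rule <- match.arg(beta_rule)
  if (n <= p) stop("need n > p")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (N < 2) stop("N must be at least 2")
  structure(list(rho = rho, p = as.integer(p), sigma = sigma,
                 n = as.integer(n), N = as.integer(N),
                 seed = as.integer(seed), beta_rule = beta_rule,
                 redraw_X = isTRUE(redraw_X)),
            class = "scenario_spec")
}

# Per-replication estimation given a precomputed canonical structure of a
# fixed design.  Returns the p x n_methods matrix of slope estimates in
# original units.  Equivalent to standardize() + canonical_transform() +
# fit_ridge() per method (asserted in the test suite); the design-only
# pieces (E, lambdas, Z, column scales) are hoisted out of the loop.
.estimate_all <- function(canon, y, methods, literal_ratio = FALSE) {
  des <- canon$design
  yc <- y - mean(y)
  zty <- drop(crossprod(canon$Z, yc))
  alpha <- zty / canon$lambdas
  rss <- sum(yc^2) - sum(zty * alpha)
  rss <- max(rss, 0)
  sigma2 <- rss / canon$df_resid
  inputs <- penalty_inputs(sigma2 = sigma2, alpha = alpha,
                           lambdas = canon$lambdas, n = canon$n, p = canon$p)
  ks <- vapply(methods, function(m) ridge_k(m, inputs, literal_ratio)$k,
               numeric(1))
  shrink <- outer(canon$lambdas, ks, function(l, k) l / (l + k))
  beta_scaled <- canon$E %*% (alpha * shrink)
  beta_scaled / des$column_scales
}

#' Run one Monte Carlo scenario
#'
#' Draws an equicorrelated Gaussian design, fixes the unit-norm true slope
#' vector (intercept 0), and over `N` replications redraws the Gaussian
#' errors, forms the response, fits all requested estimators, and
#' accumulates the squared estimation error
#' \eqn{(\hat\beta_m - \beta)'(\hat\beta_m - \beta)} over the `p` slope
#' coefficients in original predictor units.  The per-method average is the
#' estimated MSE (EMSE); its Monte Carlo standard error is also returned.
#'
#' With `redraw_X = TRUE` a fresh design is drawn per replication;
#' replications with a numerically singular design are skipped and counted
#' (more than 1\% skips is an error).
#'
#' Reproducibility: the RNG is seeded once from `spec$seed`; each
#' replication consumes draws in a fixed order independent of the method
#' set, so results for a given method do not change when other methods are
#' added or removed.
#'
#' @param spec a [scenario_spec()].
#' @param methods methods to compare (default: the full registry).
#' @param literal_ratio passed to [ridge_k()] for `NEW1`/`NEW2`.
#' @return An object of class `scenario_result`: list with `spec`, `emse`
#'   and `mc_stderr` (named numeric vectors over `methods`),
#'   `best_method`, and `skipped` (replications dropped for singular
#'   designs).
#' @export
run_scenario <- function(spec, methods = penalty_methods(),
                         literal_ratio = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  bad <- setdiff(methods, penalty_methods())
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  set.seed(spec$seed)
  Sigma <- equicorrelated_sigma(spec$p, spec$rho)
  n <- spec$n
  p <- spec$p
  X <- MASS::mvrnorm(n, rep(0, p), Sigma)
  beta <- make_beta(spec$beta_rule, p,
                    design = if (spec$redraw_X) Sigma else X)
  sq_err <- matrix(NA_real_, spec$N, length(methods),
                   dimnames = list(NULL, methods))
  skipped <- 0L
  if (!spec$redraw_X) {
    canon <- canonical_transform(standardize(
      ridge_dataset(X, rep(0, n))))
    xbeta <- drop(X %*% beta)
    for (m in seq_len(spec$N)) {
      y <- xbeta + rnorm(n, 0, spec$sigma)
      est <- .estimate_all(canon, y, methods, literal_ratio)
      sq_err[m, ] <- colSums((est - beta)^2)
    }
  } else {
    for (m in seq_len(spec$N)) {
      Xm <- MASS::mvrnorm(n, rep(0, p), Sigma)
      y <- drop(Xm %*% beta) + rnorm(n, 0, spec$sigma)
      canon <- tryCatch(
        canonical_transform(standardize(ridge_dataset(Xm, y))),
        error = function(e) {
          if (grepl("singular design", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(canon)) { skipped <- skipped + 1L; next }
      est <- .estimate_all(canon, y, methods, literal_ratio)
      sq_err[m, ] <- colSums((est - beta)^2)
    }
    if (skipped > 0.01 * spec$N)
      stop("more than 1% of replications had singular designs (",
           skipped, " of ", spec$N, ")")
  }
  ok <- stats::complete.cases(sq_err)
  sq_err <- sq_err[ok, , drop = FALSE]
  emse <- colMeans(sq_err)
  mc_stderr <- apply(sq_err, 2, stats::sd) / sqrt(nrow(sq_err))
  structure(list(
    spec = spec,
    emse = emse,
    mc_stderr = mc_stderr,
    best_method = methods[which.min(emse)],
    skipped = skipped
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 4, ...) {
  s <- x$spec
  cat(sprintf("scenario: rho=%.2f p=%d sigma=%g n=%d N=%d (seed %d)\n",
              s$rho, s$p, s$sigma, s$n, s$N, s$seed))
  tab <- data.frame(method = names(x$emse),
                    emse = round(unname(x$emse), digits),
                    mc_stderr = signif(unname(x$mc_stderr), 3))
  tab$best <- ifelse(tab$method == x$best_method, "*", "")
  print(tab, row.names = FALSE)
  if (x$skipped > 0) cat("skipped replications:", x$skipped, "\n")
  invisible(x)
}

#' Run a grid of Monte Carlo scenarios
#'
#' Runs [run_scenario()] for each spec with deterministic per-scenario
#' seeds derived from a master seed, and returns a tidy table with one row
#' per scenario x method, flagging each scenario's minimum-EMSE method.
#'
#' @param specs nonempty list of [scenario_spec()] objects.  Scenarios
#'   must be distinct in `(rho, p, sigma, n)`.
#' @param master_seed integer; per-scenario seeds are drawn from a stream
#'   seeded with it (each scenario's own `seed` field is overridden).
#' @inheritParams run_scenario
#' @return A data frame with columns `rho`, `p`, `sigma`, `n`, `N`,
#'   `method`, `emse`, `mc_stderr`, `best_flag`.
#' @export
run_grid <- function(specs, master_seed = 1, methods = penalty_methods(),
                     literal_ratio = FALSE) {
  if (!is.list(specs) || length(specs) == 0)
    stop("'specs' must be a nonempty list of scenario_spec objects")
  labels <- vapply(specs, function(s)
    paste(s$rho, s$p, s$sigma, s$n, sep = "/"), character(1))
  if (anyDuplicated(labels))
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = "; "))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    s$seed <- seeds[i]
    res <- run_scenario(s, methods = methods, literal_ratio = literal_ratio)
    data.frame(rho = s$rho, p = s$p, sigma = s$sigma, n = s$n, N = s$N,
               method = names(res$emse),
               emse = unname(res$emse),
               mc_stderr = unname(res$mc_stderr),
               best_flag = names(res$emse) == res$best_method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
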