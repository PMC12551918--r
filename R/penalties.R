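#' The fourteen-method ridge-penalty registry
#'
#' Method identifiers accepted throughout the package, in canonical order:
#' `OLS` (no shrinkage, `k = 0`), eleven published ridge rules (`HK`,
#' `HKB`, `LW`, `HSL`, `KAM`, `KGM`, `KMED`, `KS`, `KMS`, `KAG`, `SCI`),
#' and the two condition-number-adaptive proposals (`NEW1`, `NEW2`).
#'
#' @return Character vector of the 14 method identifiers.
#' @export
penalty_methods <- function() {
  c("OLS", "HK", "HKB", "LW", "HSL", "KAM", "KGM", "KMED",
    "KS", "KMS", "KAG", "SCI", "NEW1", "NEW2")
}

#' Assemble the scalar inputs shared by all penalty formulas
#'
#' Every ridge rule in the catalog is a function of the OLS residual
#' variance \eqn{\hat\sigma^2}, the canonical OLS coefficients
#' \eqn{\hat\alpha}, the eigenvalues \eqn{\lambda_i} of the standardized
#' cross-product matrix, and the dimensions `n`, `p`.
#'
#' @param canonical a [canonical_transform()] result, or `NULL` when the
#'   components are supplied directly.
#' @param sigma2,alpha,lambdas,n,p direct components (ignored when
#'   `canonical` is given).
#' @return An object of class `penalty_inputs`.
#' @export
penalty_inputs <- function(canonical = NULL, sigma2 = NULL, alpha = NULL,
                           lambdas = NULL, n = NULL, p = NULL) {
  if (!is.null(canonical)) {
    stopifnot(inherits(canonical, "canonical_fit"))
    sigma2 <- canonical$sigma2_hat
    alpha <- canonical$alpha_ols
    lambdas <- canonical$lambdas
    n <- canonical$n
    p <- canonical$p
  }
  if (length(alpha) != length(lambdas) || length(alpha) != p)
    stop("alpha and lambdas must both have length p")
  if (n <= p) stop("need n > p")
  if (any(lambdas <= 0)) stop("eigenvalues must be positive")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  structure(list(sigma2 = sigma2, alpha = alpha, lambdas = lambdas,
                 n = as.integer(n), p = as.integer(p)),
            class = "penalty_inputs")
}

#' Compute one ridge constant from the catalog
#'
#' Evaluates the named rule's formula on the canonical-fit summaries.  All
#' rules are driven by \eqn{\hat\sigma^2}, the canonical coefficients
#' \eqn{\hat\alpha_i}, and the eigenvalues \eqn{\lambda_i}:
#'
#' \describe{
#'   \item{OLS}{0 (no shrinkage).}
#'   \item{HK}{\eqn{\hat\sigma^2 / \hat\alpha_{max}^2} (Hoerl-Kennard),
#'     with \eqn{\hat\alpha_{max}^2 = \max_i \hat\alpha_i^2}.}
#'   \item{HKB}{\eqn{p\hat\sigma^2 / \sum \hat\alpha_i^2}
#'     (Hoerl-Kennard-Baldwin).}
#'   \item{LW}{\eqn{p\hat\sigma^2 / \sum \lambda_i\hat\alpha_i^2}
#'     (Lawless-Wang).}
#'   \item{HSL}{\eqn{\hat\sigma^2 \sum \lambda_i^2\hat\alpha_i^2 /
#'     (\sum \lambda_i\hat\alpha_i^2)^2} (Hocking-Speed-Lynn).}
#'   \item{KAM, KGM, KMED}{arithmetic mean, geometric mean and median of
#'     \eqn{\hat\sigma^2/\hat\alpha_i^2} (Kibria).}
#'   \item{KS}{\eqn{\hat\sigma^2\lambda_{max} / ((n-p)\hat\sigma^2 +
#'     \lambda_{max}\hat\alpha_{max}^2)} (Khalaf-Shukur).}
#'   \item{KMS}{\eqn{(\lambda_{max}/\sum|\hat\alpha_i|)\cdot
#'     \hat\sigma^2/\hat\alpha_{max}^2} (Khalaf-Mansson-Shukur).}
#'   \item{KAG}{\eqn{5\hat\sigma^2 / (\lambda_{max}\sum\hat\alpha_i^2)}
#'     (Karaibrahimoglu-Asar-Genc).}
#'   \item{SCI}{\eqn{(p+1)\hat\sigma^2} (Shabbir-Chand-Iqbal).}
#'   \item{NEW1, NEW2}{condition-number-adaptive proposals:
#'     \eqn{n \cdot k_{KAG} \cdot r^{1/(2p)}} and
#'     \eqn{n \cdot k_{KAG} \cdot r^{1/2}} with
#'     \eqn{r = \lambda_{max}/\lambda_{min}} (so \eqn{\sqrt r} is the
#'     condition number of the predictor correlation matrix).  The
#'     amount of shrinkage therefore grows with the severity of
#'     multicollinearity, the sample size and the predictor count.
#'     Setting `literal_ratio = TRUE` flips the ratio to
#'     \eqn{\lambda_{min}/\lambda_{max}}, giving penalties that shrink as
#'     collinearity worsens; this variant is retained for auditability
#'     only.}
#' }
#'
#' @param method one of [penalty_methods()].
#' @param inputs a [penalty_inputs()] object (or a `canonical_fit`, which
#'   is converted).
#' @param literal_ratio logical; use \eqn{\lambda_{min}/\lambda_{max}} in
#'   `NEW1`/`NEW2` instead of the default
#'   \eqn{\lambda_{max}/\lambda_{min}}.
#' @return An object of class `penalty_value`: list with `method` and `k`.
#' @examples
#' inp <- penalty_inputs(sigma2 = 1.5, alpha = c(0.8, -0.5, 0.3, -0.2),
#'                       lambdas = c(2.5, 0.8, 0.5, 0.2), n = 20, p = 4)
#' ridge_k("HKB", inp)
#' @export
ridge_k <- function(method, inputs, literal_ratio = FALSE) {
  if (inherits(inputs, "canonical_fit")) inputs <- penalty_inputs(inputs)
  stopifnot(inherits(inputs, "penalty_inputs"))
  registry <- penalty_methods()
  if (!is.character(method) || length(method) != 1 || !method %in% registry)
    stop("unknown method '", method, "'; registry: ",
         paste(registry, collapse = ", "))
  s <- inputs$sigma2
  a <- inputs$alpha
  l <- inputs$lambdas
  n <- inputs$n
  p <- inputs$p
  a2 <- a^2
  amax2 <- max(a2)
  lmax <- max(l)
  lmin <- min(l)
  needs_all_alpha <- c("HK", "KAM", "KGM", "KMED", "KMS")
  if (method %in% needs_all_alpha && any(a2 == 0))
    stop("degenerate canonical coefficient: alpha[",
         which(a2 == 0)[1], "] = 0 for method ", method)
  k <- switch(method,
    OLS  = 0,
    HK   = s / amax2,
    HKB  = p * s / sum(a2),
    LW   = p * s / sum(l * a2),
    HSL  = s * sum(l^2 * a2) / sum(l * a2)^2,
    KAM  = (s / p) * sum(1 / a2),
    # geometric mean via log scale to avoid under/overflow of prod(a^2)
    KGM  = s / exp(mean(log(a2))),
    KMED = stats::median(s / a2),
    KS   = s * lmax / ((n - p) * s + lmax * amax2),
    KMS  = (lmax / sum(abs(a))) * (s / amax2),
    KAG  = 5 * s / (lmax * sum(a2)),
    SCI  = (p + 1) * s,
    NEW1 = ,
    NEW2 = {
      kag <- 5 * s / (lmax * sum(a2))
      r <- if (literal_ratio) lmin / lmax else lmax / lmin
      expo <- if (method == "NEW1") 1 / (2 * p) else 1 / 2
      n * kag * r^expo
    }
  )
  if (!is.finite(k) || k < 0)
    stop("method ", method, " produced a non-finite or negative k")
  structure(list(method = method, k = k), class = "penalty_value")
}

#' Evaluate every (or a chosen subset of) ridge rules
#'
#' @param canonical a [canonical_transform()] result.
#' @param methods character vector of method identifiers
#'   (default: the full registry).
#' @inheritParams ridge_k
#' @return A data frame with columns `method` and `k`, one row per method,
#'   in registry order.
#' @export
all_penalties <- function(canonical, methods = penalty_methods(),
                          literal_ratio = FALSE) {
  inputs <- penalty_inputs(canonical)
  bad <- setdiff(methods, penalty_methods())
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; registry: ", paste(penalty_methods(), collapse = ", "))
  ks <- vapply(methods, function(m) ridge_k(m, inputs, literal_ratio)$k,
               numeric(1))
  data.frame(method = methods, k = unname(ks), stringsAsFactors = FALSE)
}

#' @export
print.penalty_value <- function(x, ...) {
  cat("penalty_value:", x$method, "k =", format(x$k), "\n")
  invisible(x)
}
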