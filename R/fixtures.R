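#' Shipped predictor correlation matrices
#'
#' Two published predictor correlation matrices, transcribed to 4 decimal
#' places, used as test fixtures for the collinearity diagnostics:
#'
#' * `bodyfat_cor()`: 13 anthropometric predictors (circumferences,
#'   weight, height, body density) from a 50-person body-fat study —
#'   strong multicollinearity (largest VIF near 96).
#' * `livestock_cor()`: 5 national livestock-population predictors from an
#'   18-year economic survey — extreme multicollinearity (all pairwise
#'   correlations above 0.94; smallest eigenvalue near 1e-5, so
#'   eigenvalue-ratio summaries of this matrix are very sensitive to the
#'   4-decimal rounding of the printed entries).
#'
#' @return A p x p correlation matrix with named rows/columns.
#' @name fixture_matrices
NULL

read_cor_fixture <- function(file) {
  path <- system.file("extdata", file, package = "ridgepen", mustWork = TRUE)
  M <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(M) <- colnames(M)
  # symmetrize away any residual asymmetry from transcription order
  (M + t(M)) / 2
}

#' @rdname fixture_matrices
#' @export
bodyfat_cor <- function() read_cor_fixture("bodyfat_cor.csv")

#' @rdname fixture_matrices
#' @export
livestock_cor <- function() read_cor_fixture("livestock_cor.csv")

#' Write a reusable fixture to disk
#'
#' Three kinds: `"simulated"` draws one dataset from the Monte Carlo
#' scheme of [run_scenario()] (equicorrelated Gaussian predictors,
#' unit-norm slope vector, Gaussian errors) and writes it as a CSV with a
#' JSON sidecar recording the seed and true coefficients;
#' `"bodyfat_cor"` / `"livestock_cor"` write the shipped correlation
#' matrices.
#'
#' @param kind `"simulated"`, `"bodyfat_cor"` or `"livestock_cor"`.
#' @param path output CSV path (the sidecar, for `"simulated"`, is
#'   `paste0(path, ".meta.json")`).
#' @param spec a [scenario_spec()]; required for `"simulated"`.
#' @return The output path, invisibly.
#' @export
make_fixture <- function(kind, path, spec = NULL) {
  kind <- as.character(kind)
  if (kind == "simulated") {
    if (is.null(spec)) stop("kind 'simulated' requires a scenario spec")
    stopifnot(inherits(spec, "scenario_spec"))
    set.seed(spec$seed)
    Sigma <- equicorrelated_sigma(spec$p, spec$rho)
    X <- MASS::mvrnorm(spec$n, rep(0, spec$p), Sigma)
    beta <- make_beta(spec$beta_rule, spec$p,
                      design = if (spec$redraw_X) Sigma else X)
    y <- drop(X %*% beta) + rnorm(spec$n, 0, spec$sigma)
    df <- data.frame(X, y = y)
    names(df) <- c(paste0("X", seq_len(spec$p)), "y")
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(kind = "simulated", rho = spec$rho, p = spec$p,
                 sigma = spec$sigma, n = spec$n, seed = spec$seed,
                 beta_rule = spec$beta_rule, beta_true = beta,
                 intercept_true = 0)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (kind %in% c("bodyfat_cor", "livestock_cor")) {
    M <- if (kind == "bodyfat_cor") bodyfat_cor() else livestock_cor()
    utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  } else {
    stop("unknown fixture kind '", kind,
         "'; use simulated, bodyfat_cor or livestock_cor")
  }
  invisible(path)
}

#' Render a scenario-grid result as an aligned text table
#'
#' Formats the tidy table produced by [run_grid()] with one row per
#' scenario, one column per method, and the per-row minimum EMSE flagged
#' with an asterisk.
#'
#' @param results data frame from [run_grid()] (or [run_scenario()]
#'   results coerced through it).
#' @return Character vector of formatted lines, invisibly; also printed.
#' @export
render_report <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("'results' must be a nonempty data frame")
  req <- c("rho", "p", "sigma", "n", "method", "emse", "best_flag")
  if (!all(req %in% names(results)))
    stop("missing columns: ", paste(setdiff(req, names(results)), collapse = ", "))
  key <- interaction(results$rho, results$p, results$sigma, results$n,
                     drop = TRUE)
  methods <- unique(results$method)
  lines <- sprintf("%-22s %s", "scenario",
                   paste(sprintf("%10s", methods), collapse = ""))
  for (g in levels(key)) {
    sub <- results[key == g, ]
    cells <- vapply(methods, function(m) {
      r <- sub[sub$method == m, ]
      if (nrow(r) == 0) return(sprintf("%10s", "-"))
      sprintf("%9.4f%s", r$emse, if (isTRUE(r$best_flag)) "*" else " ")
    }, character(1))
    lab <- sprintf("rho=%g p=%d s=%g n=%d", sub$rho[1], sub$p[1],
                   sub$sigma[1], sub$n[1])
    lines <- c(lines, sprintf("%-22s %s", lab, paste(cells, collapse = "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
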