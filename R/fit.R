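#' Fit a response by ordinary least squares
#'
#' Solves the least-squares problem for one response against the model matrix
#' of a spec, by QR decomposition (no intercept column is added: Scheffe-type
#' specs absorb the intercept through the mixture sum constraint). The ANOVA
#' summary follows the mean-corrected convention for intercept-absorbing
#' mixture models: total sum of squares about the response mean, regression
#' degrees of freedom equal to the term count minus one.
#'
#' @param data study data frame; rows with the response missing are dropped.
#' @param spec a [model_spec()].
#' @param response response column name (`ps_nm`, `pdi` or `zp_abs_mv` in the
#'   packaged study).
#' @param process_coding passed to [model_matrix()].
#' @return an `sln_fit` with coefficients, standard errors, residuals, fitted
#'   values, `sse`, `sst`, `r2`, `f_stat`, `p_value` and degrees of freedom.
#' @examples
#' fit <- fit_response(design_runs(sln_runs()), model_spec(), "ps_nm")
#' round(fit$r2, 2)
#' @export
fit_response <- function(data, spec, response, process_coding = "centered") {
  if (!response %in% names(data)) stop_data(paste("no response column", response))
  ok <- !is.na(data[[response]])
  data <- data[ok, , drop = FALSE]
  y <- data[[response]]
  p <- length(spec$terms)
  if (length(y) < p)
    stop_config(sprintf("%d usable runs for '%s' but the '%s' spec needs at least %d",
                        length(y), response, spec$name, p))
  X <- model_matrix(data, spec, process_coding)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- spec$labels[sort(qx$pivot[(qx$rank + 1):p])]
    stop_numeric(paste("model matrix is rank-deficient; collinear terms:",
                       paste(bad, collapse = ", ")))
  }
  coeffs <- qr.coef(qx, y)
  fitted <- drop(X %*% coeffs)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df_model <- p - 1L
  df_resid <- length(y) - p
  sigma2 <- if (df_resid > 0) sse / df_resid else NA_real_
  se <- if (df_resid > 0) {
    R <- qr.R(qx)[, order(qx$pivot), drop = FALSE]
    sqrt(diag(chol2inv(R)) * sigma2)
  } else rep(NA_real_, p)
  names(se) <- spec$labels
  fit <- structure(list(
    spec = spec, response = response, process_coding = process_coding,
    coeffs = coeffs, se = se, fitted = fitted, residuals = res,
    run_id = data$run_id, n = length(y),
    sse = sse, sst = sst, r2 = 1 - sse / sst,
    df_model = df_model, df_resid = df_resid, sigma2 = sigma2),
    class = "sln_fit")
  an <- tryCatch(anova_regression(fit), sln_numeric_error = function(e) NULL)
  if (!is.null(an)) {
    fit$f_stat <- an$f_stat
    fit$p_value <- an$p_value
  }
  fit
}

#' Regression ANOVA summary
#'
#' F-test of the whole regression: `F = (SSR/df_model) / (SSE/df_resid)` with
#' `SSR = SST - SSE`, total sum of squares mean-corrected; the p-value is the
#' upper tail of the F distribution. Reported as a probability in \[0, 1\]
#' (multiply by 100 for the percent form some reports print).
#'
#' @param fit an `sln_fit`.
#' @return list with `f_stat`, `p_value`, `r2`.
#' @export
anova_regression <- function(fit) {
  if (fit$df_resid < 1) stop_config("no residual degrees of freedom")
  if (fit$sst <= 0) stop_numeric("degenerate (constant) response: total sum of squares is zero")
  f <- ((fit$sst - fit$sse) / fit$df_model) / (fit$sse / fit$df_resid)
  list(f_stat = f,
       p_value = stats::pf(f, fit$df_model, fit$df_resid, lower.tail = FALSE),
       r2 = fit$r2)
}

#' Predict a fitted response at new conditions
#'
#' @param object an `sln_fit`.
#' @param newdata run conditions (columns `p80_pct`, `us_time_min`, `cw`,
#'   `gb`, `gds`).
#' @param extrapolate allow process settings outside the variation domains.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.sln_fit <- function(object, newdata, extrapolate = FALSE, ...) {
  if (!extrapolate) {
    code_process(newdata$p80_pct, newdata$us_time_min) # domain check only
    validate_conditions(newdata)
  }
  drop(model_matrix(newdata, object$spec, object$process_coding) %*% object$coeffs)
}

#' @export
print.sln_fit <- function(x, ...) {
  cat(sprintf("<sln_fit: %s ~ %s (%d terms), n = %d>\n",
              x$response, x$spec$name, length(x$spec$terms), x$n))
  cat(sprintf("  R2 = %.4f  F(%d, %d) = %.3f  p = %.3g\n",
              x$r2, x$df_model, x$df_resid,
              x$f_stat %||% NA_real_, x$p_value %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled experimental variance from repeated runs
#'
#' Groups runs with identical conditions and pools their within-group
#' variances: `s2 = sum((n_g - 1) s2_g) / sum(n_g - 1)`. For duplicated pairs
#' this is the mean of the squared differences over two, with one degree of
#' freedom per pair.
#'
#' @param data study data frame.
#' @param response response column name.
#' @return list with `pooled_variance` and `df`.
#' @export
replicate_variance <- function(data, response) {
  y <- data[[response]]
  key <- apply(signif(as.matrix(data[, .run_cols[-1]]), 10), 1, paste, collapse = "|")
  groups <- split(y[!is.na(y)], key[!is.na(y)])
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) stop_data("no condition-identical repeated runs in the data")
  df <- vapply(groups, function(g) length(g) - 1L, 1L)
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), 1)
  list(pooled_variance = sum(ss) / sum(df), df = sum(df))
}

#' Serialize and restore fit reports
#'
#' Round-trip stable YAML report: term labels, coefficients, standard errors,
#' fit statistics and degrees of freedom.
#'
#' @param fit an `sln_fit`.
#' @param path file path.
#' @return `fit_report()`: a plain list. `write_fit_report()`: `path`,
#'   invisibly.
#' @export
fit_report <- function(fit) {
  list(response = fit$response,
       model = fit$spec$name,
       process_coding = fit$process_coding,
       n = fit$n,
       terms = as.list(stats::setNames(as.numeric(fit$coeffs), fit$spec$labels)),
       se = as.list(stats::setNames(as.numeric(fit$se), fit$spec$labels)),
       r2 = fit$r2, f_stat = fit$f_stat %||% NA_real_,
       p_value = fit$p_value %||% NA_real_,
       df_model = fit$df_model, df_resid = fit$df_resid)
}

#' @rdname fit_report
#' @export
write_fit_report <- function(fit, path) {
  yaml::write_yaml(fit_report(fit), path, precision = 15)
  invisible(path)
}
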