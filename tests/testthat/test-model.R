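test_that("QR fit agrees with a normal-equations oracle", {
  spec <- model_spec("scheffe_reduced_cubic")
  for (seed in c(1, 5, 23)) {
    runs <- random_conditions(25, seed = seed)
    set.seed(seed + 1)
    runs$ps_nm <- stats::runif(25, 50, 400)
    fit <- fit_response(runs, spec, "ps_nm")
    oracle <- ols_normal_equations(model_matrix(runs, spec), runs$ps_nm)
    expect_equal(unname(fit$coeffs), drop(oracle), tolerance = 1e-8)
  }
})

test_that("fit summaries satisfy the OLS identities", {
  study <- sln_runs()
  fit <- fit_response(study, model_spec(), "ps_nm")
  expect_equal(fit$n, 66)
  expect_equal(fit$df_resid, 66 - 28)
  expect_equal(fit$df_model, 27)
  expect_gte(fit$r2, 0)
  expect_lte(fit$r2, 1)
  # residual orthogonality to every model-matrix column
  X <- model_matrix(study, model_spec())
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-6 * max(abs(X)) * max(abs(study$ps_nm)))
  # prediction at a design run equals the fitted value
  expect_equal(predict(fit, study[12, ]), study$ps_nm[12] - fit$residuals[12],
               tolerance = 1e-10)
  expect_equal(fit$sse, sum(fit$residuals^2))
  an <- anova_regression(fit)
  expect_equal(an$r2, fit$r2)
  expect_equal(an$p_value,
               stats::pf(an$f_stat, 27, 38, lower.tail = FALSE))
})

test_that("scaling a response scales coefficients but not R2, F or p", {
  study <- design_runs(sln_runs())
  f1 <- fit_response(study, model_spec(), "ps_nm")
  scaled <- study
  scaled$ps_nm <- scaled$ps_nm * 3.7
  f2 <- fit_response(scaled, model_spec(), "ps_nm")
  expect_equal(f2$coeffs, f1$coeffs * 3.7, tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  expect_equal(f2$f_stat, f1$f_stat, tolerance = 1e-9)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-9)
  at <- table4_condition()
  expect_equal(predict(f2, at), predict(f1, at) * 3.7, tolerance = 1e-9)
})

test_that("predictions are invariant to the process-factor coding", {
  study <- design_runs(sln_runs())
  f_centered <- fit_response(study, model_spec(), "ps_nm", process_coding = "centered")
  f_unit <- fit_response(study, model_spec(), "ps_nm", process_coding = "unit")
  probe <- random_conditions(100, seed = 77)
  expect_equal(predict(f_centered, probe), predict(f_unit, probe), tolerance = 1e-6)
})

test_that("degenerate inputs raise typed errors", {
  study <- design_runs(sln_runs())
  expect_error(fit_response(study[1:20, ], model_spec(), "ps_nm"),
               class = "sln_config_error")
  expect_error(fit_response(study, model_spec(), "nope"), class = "sln_data_error")

  const <- study
  const$ps_nm <- 100
  fitc <- fit_response(const, model_spec(), "ps_nm")
  expect_error(anova_regression(fitc), class = "sln_numeric_error")

  # no GDS anywhere: every x5-bearing column vanishes, and the error names one
  flat <- sln_runs()
  flat <- flat[flat$gds == 0, ] # 30 rows, so rank (not size) is what fails
  err <- tryCatch(fit_response(flat, model_spec(), "ps_nm"), error = identity)
  expect_s3_class(err, "sln_numeric_error")
  expect_match(conditionMessage(err), "x5")
})

test_that("pooled replicate variance follows the paired formula", {
  study <- sln_runs()
  rv <- replicate_variance(study, "ps_nm")
  # hand-applied pooled-pairs formula on the three repeated runs
  pairs <- list(c(113.9, 111.2), c(98.83, 131.2), c(142.3, 128.3))
  expected <- sum(vapply(pairs, function(p) diff(p)^2 / 2, 1)) / 3
  expect_equal(rv$pooled_variance, expected, tolerance = 1e-12)
  expect_equal(rv$df, 3L)
  expect_equal(expected, 208.5178, tolerance = 1e-4)

  ident <- study[c(1, 1), ]
  expect_equal(replicate_variance(ident, "ps_nm")$pooled_variance, 0)
  expect_error(replicate_variance(design_runs(study), "ps_nm"),
               class = "sln_data_error")
})

test_that("coefficient estimates are unbiased at the experimental noise level", {
  spec <- model_spec()
  design <- design_runs(sln_runs())
  beta <- fit_response(design, spec, "ps_nm")$coeffs
  sd_exp <- sqrt(replicate_variance(sln_runs(), "ps_nm")$pooled_variance)
  n_sim <- 200
  est <- matrix(NA_real_, n_sim, length(beta))
  for (s in seq_len(n_sim)) {
    sim <- simulate_responses(design, spec, beta, noise_sd = sd_exp, seed = 1000 + s,
                              responses = "ps_nm")
    est[s, ] <- fit_response(sim, spec, "ps_nm")$coeffs
  }
  bias <- colMeans(est) - beta
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_sim)
  expect_true(all(abs(bias) <= 3 * mc_se))
})

test_that("fit reports round-trip through YAML", {
  fit <- fit_response(design_runs(sln_runs()), model_spec(), "zp_abs_mv")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_fit_report(fit, tmp)
  back <- yaml::read_yaml(tmp)
  expect_equal(back$r2, fit$r2, tolerance = 1e-12)
  expect_equal(unlist(back$terms), stats::setNames(as.numeric(fit$coeffs), fit$spec$labels),
               tolerance = 1e-12)
  expect_equal(back$df_resid, fit$df_resid)
})
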