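test_that("all true-dose estimators coincide at zero Berkson error", {
  g <- small_groups()
  cfg <- error_config(classical_shared = 0.2, classical_unshared = 0.2)
  risk <- risk_model_spec("linear-quadratic")
  ens <- build_ensemble(g, cfg, risk, m = 20, seed = 4)
  rc <- fit_regression_calibration(ens$cohort, ens$doses, "linear-quadratic")
  erc <- fit_erc(ens$cohort, ens$doses, "linear-quadratic")
  mcml <- fit_mcml(ens$cohort, ens$doses, "linear-quadratic")
  direct <- fit_mle(ens$cohort, g$central_doses, "linear-quadratic")
  for (f in list(erc, mcml)) {
    expect_equal(f$alpha_hat, rc$alpha_hat, tolerance = 1e-6)
    expect_equal(f$beta_hat, rc$beta_hat, tolerance = 1e-6)
  }
  expect_equal(rc$alpha_hat, direct$alpha_hat, tolerance = 1e-8)
  # ERC reduces exactly to RC (zero between-realization spread)
  expect_equal(erc$ci_alpha, rc$ci_alpha)
  expect_equal(erc$ci_beta, rc$ci_beta)
})

test_that("classical error never touches the true-dose estimators", {
  g <- small_groups()
  risk <- risk_model_spec("linear-quadratic")
  cfg1 <- error_config(berkson_shared = 0.5, berkson_unshared = 0.2,
                       classical_shared = 0.2, classical_unshared = 0.2)
  cfg2 <- error_config(berkson_shared = 0.5, berkson_unshared = 0.2,
                       classical_shared = 0.5, classical_unshared = 0.5)
  e1 <- build_ensemble(g, cfg1, risk, m = 25, seed = 9)
  e2 <- build_ensemble(g, cfg2, risk, m = 25, seed = 9)
  expect_identical(e1$doses, e2$doses)
  expect_identical(e1$cohort, e2$cohort)
  f1 <- fit_regression_calibration(e1$cohort, e1$doses, "linear-quadratic")
  f2 <- fit_regression_calibration(e2$cohort, e2$doses, "linear-quadratic")
  expect_identical(f1, f2)
  b1 <- run_quasi_2dmc_bma(e1$cohort, e1$doses, "linear-quadratic", seed = 2)
  b2 <- run_quasi_2dmc_bma(e2$cohort, e2$doses, "linear-quadratic", seed = 2)
  expect_identical(b1$fit$alpha_hat, b2$fit$alpha_hat)
  m1 <- fit_fma(e1$cohort, e1$doses, "linear-quadratic", seed = 2)
  m2 <- fit_fma(e2$cohort, e2$doses, "linear-quadratic", seed = 2)
  expect_identical(m1$alpha_hat, m2$alpha_hat)
  # the unadjusted fit DOES change with classical error
  u1 <- fit_unadjusted(e1$cohort, e1, "linear-quadratic")
  u2 <- fit_unadjusted(e2$cohort, e2, "linear-quadratic")
  expect_false(isTRUE(all.equal(u1$alpha_hat, u2$alpha_hat)))
  # ... and conversely ignores Berkson-only changes under the same seed
  cfg3 <- error_config(berkson_shared = 0.2, berkson_unshared = 0.5,
                       classical_shared = 0.2, classical_unshared = 0.2)
  e3 <- build_ensemble(g, cfg3, risk, m = 25, seed = 9)
  expect_identical(e1$unadjusted_doses, e3$unadjusted_doses)
})

test_that("unadjusted fit at zero error equals the central-dose fit", {
  g <- small_groups()
  ens <- build_ensemble(g, error_config(), risk_model_spec("linear"),
                        m = 3, seed = 5)
  u <- fit_unadjusted(ens$cohort, ens, "linear")
  direct <- fit_mle(ens$cohort, g$central_doses, "linear")
  expect_equal(u$alpha_hat, direct$alpha_hat)
  expect_equal(u$ci_alpha, direct$ci_alpha)
})

test_that("single-realization dose sets make RC, ERC and MCML identical", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.4, berkson_unshared = 0.3)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 1, seed = 7)
  rc <- fit_regression_calibration(ens$cohort, ens$doses, "linear-quadratic")
  erc <- fit_erc(ens$cohort, ens$doses, "linear-quadratic")
  mcml <- fit_mcml(ens$cohort, ens$doses, "linear-quadratic")
  expect_equal(erc$alpha_hat, rc$alpha_hat)
  expect_equal(erc$ci_alpha, rc$ci_alpha)
  expect_match(erc$diagnostics$inflation, "skipped")
  expect_equal(mcml$alpha_hat, rc$alpha_hat, tolerance = 1e-5)
  expect_equal(mcml$loglik, rc$loglik, tolerance = 1e-8)
})

test_that("ERC intervals widen under shared Berkson error", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.5)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 40, seed = 3)
  rc <- fit_regression_calibration(ens$cohort, ens$doses, "linear-quadratic")
  erc <- fit_erc(ens$cohort, ens$doses, "linear-quadratic")
  expect_equal(erc$alpha_hat, rc$alpha_hat)
  expect_gt(diff(erc$ci_alpha), diff(rc$ci_alpha))
  expect_gt(diff(erc$ci_beta), diff(rc$ci_beta))
  expect_gt(erc$diagnostics$between_var_alpha, 0)
})

test_that("the MCML objective matches brute-force likelihood averaging", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.3, berkson_unshared = 0.3)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 15, seed = 8)
  co <- ens$cohort
  D <- ens$doses$vectors
  const <- sum(co$cases * log(co$person_years)) - sum(lgamma(co$cases + 1))
  for (theta in list(c(0.25, 2, -4), c(1, 0.5, -3.5), c(0, 0, -4.2))) {
    brute <- log(mean(vapply(seq_len(nrow(D)), function(k)
      exp(rr_loglik(theta[1], theta[2], theta[3], co, D[k, ])),
      numeric(1))))
    expect_equal(doserr:::mcml_objective(theta, co, D, FALSE, const),
                 brute, tolerance = 1e-9)
    # bounded by the extreme per-vector log-likelihoods
    lls <- vapply(seq_len(nrow(D)), function(k)
      rr_loglik(theta[1], theta[2], theta[3], co, D[k, ]), numeric(1))
    obj <- doserr:::mcml_objective(theta, co, D, FALSE, const)
    expect_gte(obj, min(lls) - 1e-9)
    expect_lte(obj, max(lls) + 1e-9)
  }
})
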