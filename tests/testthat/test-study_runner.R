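fake_fit <- function(ci_a, ci_b = NULL, alpha = mean(ci_a),
                     beta = if (is.null(ci_b)) NA_real_ else mean(ci_b),
                     converged = TRUE) {
  structure(list(method = "x", form = "linear-quadratic", alpha_hat = alpha,
                 beta_hat = beta, kappa_hat = 0, loglik = -1, aic = 8,
                 npar = 3L, ci_alpha = ci_a, ci_beta = ci_b,
                 converged = converged, diagnostics = list()),
            class = "doserr_fit")
}

test_that("coverage counts interval hits and exclusions", {
  fits <- list(fake_fit(c(-Inf, Inf)), fake_fit(c(0, 1)),
               fake_fit(c(5, 6)), fake_fit(c(0, 1), converged = FALSE))
  cv <- coverage(fits, 0.5, "alpha")
  expect_equal(as.numeric(cv), 100 * 2 / 3)
  expect_equal(attr(cv, "n_used"), 3L)
  expect_equal(attr(cv, "n_excluded"), 1L)
  expect_equal(as.numeric(coverage(list(fake_fit(c(-Inf, Inf))), 99)), 100)
  expect_equal(as.numeric(coverage(list(fake_fit(c(5, 6))), 0.5)), 0)
  # widening every interval never decreases coverage
  fits2 <- lapply(fits, function(f) {
    f$ci_alpha <- f$ci_alpha + c(-1, 1); f
  })
  expect_gte(as.numeric(coverage(fits2, 0.5)), as.numeric(coverage(fits, 0.5)))
  expect_error(coverage(list(), 1), "usable")
})

test_that("mean coefficients average converged fits", {
  fits <- list(fake_fit(c(0, 2), alpha = 1), fake_fit(c(2, 4), alpha = 3),
               fake_fit(c(0, 1), alpha = 99, converged = FALSE))
  expect_equal(unname(mean_coefficients(fits)["alpha_mean"]), 2)
  expect_equal(unname(mean_coefficients(fits[1])["alpha_mean"]), 1)
})

test_that("percent bias in the excess relative risk is exact", {
  lq <- risk_model_spec("linear-quadratic", alpha = 0.25, beta = 2)
  expect_equal(err_bias(0.25, 2, lq, 0.7), 0)
  lin <- risk_model_spec("linear", alpha = 3)
  # linear bias is dose-independent
  expect_equal(err_bias(3.345, 0, lin, 0.1), err_bias(3.345, 0, lin, 1))
  expect_equal(err_bias(3.345, 0, lin, 1), 11.5)
  expect_error(err_bias(1, 1, risk_model_spec("linear", alpha = 0), 1),
               "not positive")
})

test_that("a one-ensemble study populates every table deterministically", {
  cfgs <- list(low = error_config(berkson_shared = 0.2,
                                  berkson_unshared = 0.2,
                                  classical_shared = 0.2,
                                  classical_unshared = 0.2))
  sc <- study_config(n_meta = 1, m_sub = 8, scenarios = cfgs,
                     methods = c("unadjusted", "regression_calibration",
                                 "erc", "fma"),
                     risk_models = list(risk_model_spec("linear-quadratic")),
                     groups = small_groups(),
                     bma = bma_settings(n_burnin = 50, n_keep = 50),
                     master_seed = 5)
  r1 <- run_study(sc)
  r2 <- run_study(sc)
  expect_equal(r1$coverage, r2$coverage)
  expect_equal(r1$mean_coefs, r2$mean_coefs)
  expect_true(all(r1$coverage$coverage %in% c(0, 100)))
  expect_equal(nrow(r1$coverage), 8)       # 4 methods x 2 coefficients
  expect_equal(nrow(r1$err_bias), 8)       # 4 methods x 2 pred doses
  expect_equal(nrow(r1$dose_correlations), 1)
})

test_that("study cells for true-dose methods are identical across classical scenarios", {
  cfgs <- list(c20 = error_config(berkson_shared = 0.3,
                                  classical_shared = 0.2,
                                  classical_unshared = 0.2),
               c50 = error_config(berkson_shared = 0.3,
                                  classical_shared = 0.5,
                                  classical_unshared = 0.5))
  sc <- study_config(n_meta = 2, m_sub = 6, scenarios = cfgs,
                     methods = c("unadjusted", "regression_calibration"),
                     risk_models = list(risk_model_spec("linear")),
                     groups = small_groups(), master_seed = 3)
  r <- run_study(sc)
  rc <- r$mean_coefs[r$mean_coefs$method == "regression_calibration", ]
  expect_equal(rc$alpha_mean[rc$scenario == "c20"],
               rc$alpha_mean[rc$scenario == "c50"])
  un <- r$mean_coefs[r$mean_coefs$method == "unadjusted", ]
  expect_false(isTRUE(all.equal(un$alpha_mean[un$scenario == "c20"],
                                un$alpha_mean[un$scenario == "c50"])))
})

test_that("steering files parse, reject unknown keys, and round-trip", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[study]", "n_meta = 12", "methods = regression_calibration",
               "", "[scenario berk50]", "berkson_shared = 50%",
               "berkson_unshared = 0.2"), path)
  sc <- read_steering(path)
  expect_equal(sc$n_meta, 12L)
  expect_equal(sc$methods, "regression_calibration")
  expect_equal(sc$scenarios$berk50$berkson_shared, 0.5)   # percent form
  expect_equal(sc$scenarios$berk50$berkson_unshared, 0.2) # proportion form
  expect_equal(sc$m_sub, 1000L)                           # default filled
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[study]", "n_meta = 5", "frobnicate = 1"), bad)
  expect_error(read_steering(bad), "line 3: unknown key 'frobnicate'")

  full <- study_config(n_meta = 7, m_sub = 11, groups = small_groups(),
                       methods = c("erc", "fma"), master_seed = 99)
  rt <- withr::local_tempfile(fileext = ".cfg")
  write_steering(full, rt)
  back <- read_steering(rt)
  for (field in c("n_meta", "m_sub", "n_cases", "fma_k", "pred_doses",
                  "master_seed", "methods")) {
    expect_equal(back[[field]], full[[field]], info = field)
  }
  expect_equal(back$groups$central_doses, full$groups$central_doses)
  expect_equal(back$groups$n_individuals, full$groups$n_individuals)
  expect_equal(lapply(back$scenarios, unclass),
               lapply(full$scenarios, unclass))
  expect_equal(unclass(back$bma), unclass(full$bma))
})

test_that("result tables round-trip through CSV", {
  cfgs <- list(one = error_config(berkson_shared = 0.2,
                                  classical_shared = 0.2,
                                  classical_unshared = 0.2))
  sc <- study_config(n_meta = 1, m_sub = 5, scenarios = cfgs,
                     methods = "regression_calibration",
                     groups = small_groups(), master_seed = 2)
  r <- run_study(sc)
  out <- withr::local_tempdir()
  paths <- write_tables(r, out)
  expect_true(all(file.exists(paths)))
  lq <- read.csv(file.path(out, "table_coverage_lq.csv"))
  expect_equal(nrow(lq), 1)
  got <- lq$regression_calibration_alpha_coverage
  want <- r$coverage$coverage[r$coverage$form != "linear" &
                                r$coverage$coefficient == "alpha"]
  expect_equal(got, want)
  lin <- read.csv(file.path(out, "table_mean_coefs_linear.csv"))
  expect_equal(lin$regression_calibration_alpha_mean,
               r$mean_coefs$alpha_mean[r$mean_coefs$form == "linear"])
})
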