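test_that("softmax probabilities are exact, normalized and shift-invariant", {
  expect_equal(softmax_probs(numeric(0)), 1)
  expect_equal(softmax_probs(log(2)), c(2 / 3, 1 / 3))
  p <- softmax_probs(rep(0, 999))
  expect_length(p, 1000)
  expect_equal(p, rep(1 / 1000, 1000))
  expect_equal(sum(softmax_probs(rnorm(50, 0, 30))), 1, tolerance = 1e-12)
})

test_that("mixture log-likelihood honours its degeneracies and a brute-force oracle", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.4, berkson_unshared = 0.2)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 12, seed = 2)
  co <- ens$cohort; ds <- ens$doses
  # concentrated on one vector: equals that vector's log-likelihood
  p <- rep(0, 12); p[5] <- 1
  expect_equal(mixture_log_likelihood(0.3, 1.5, -4, p, co, ds),
               rr_loglik(0.3, 1.5, -4, co, ds$vectors[5, ]))
  # uniform weights: equals the MCML objective
  const <- sum(co$cases * log(co$person_years)) - sum(lgamma(co$cases + 1))
  expect_equal(mixture_log_likelihood(0.3, 1.5, -4, rep(1 / 12, 12), co, ds),
               doserr:::mcml_objective(c(0.3, 1.5, -4), co, ds$vectors,
                                       FALSE, const), tolerance = 1e-9)
  # arbitrary weights against direct summation
  w <- softmax_probs(rnorm(11, 0, 1))
  brute <- log(sum(w * vapply(seq_len(12), function(k)
    exp(rr_loglik(0.2, 2.2, -4.1, co, ds$vectors[k, ])), numeric(1))))
  expect_equal(mixture_log_likelihood(0.2, 2.2, -4.1, w, co, ds), brute,
               tolerance = 1e-9)
})

test_that("BGR statistic matches a hand computation and flags degeneracy", {
  # two identical chains: sqrt((n-1)/n)
  ch <- list(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  expect_equal(bgr_statistic(ch), sqrt(9 / 10))
  # hand-computed toy value on two 10-draw chains
  c1 <- c(0.1, 0.4, 0.2, 0.5, 0.3, 0.1, 0.4, 0.2, 0.5, 0.3)
  c2 <- c1 + 2
  n <- 10
  W <- (var(c1) + var(c2)) / 2
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(bgr_statistic(list(c1, c2)),
               sqrt((W * (n - 1) / n + B / n) / W))
  expect_gt(bgr_statistic(list(c1, c2)), 5)  # separated chains blow up
  expect_warning(r <- bgr_statistic(list(rep(1, 10), rep(1, 10))), "zero")
  expect_true(is.nan(r))
})

test_that("single-vector BMA posterior tracks the single-model fit", {
  g <- small_groups()
  ens <- build_ensemble(g, error_config(), risk_model_spec("linear"),
                        m = 1, seed = 6)
  mle <- fit_mle(ens$cohort, ens$doses$mean_vector, "linear")
  s <- bma_settings(n_burnin = 2000, n_keep = 4000)
  b <- run_quasi_2dmc_bma(ens$cohort, ens$doses, "linear", settings = s,
                          seed = 3)
  expect_equal(unname(b$summary$p_weights_mean), 1)
  # with a nearly flat prior the posterior concentrates near the MLE
  post_sd <- diff(b$summary$ci_alpha) / (2 * 1.96)
  expect_lt(abs(b$summary$mean_alpha - mle$alpha_hat), 3 * post_sd)
  expect_true(b$summary$ci_alpha[1] < mle$alpha_hat &&
                mle$alpha_hat < b$summary$ci_alpha[2])
})

test_that("lambda posterior is exchangeable when all dose vectors coincide", {
  g <- small_groups()
  ens <- build_ensemble(g, error_config(classical_shared = 0.2),
                        risk_model_spec("linear-quadratic"), m = 4, seed = 2)
  # a tight lambda prior keeps the weight walk near the origin, where the
  # exchangeable posterior mean is estimable from a short run
  s <- bma_settings(prior_sd = 2, n_burnin = 1000, n_keep = 4000)
  b <- run_quasi_2dmc_bma(ens$cohort, ens$doses, "linear-quadratic",
                          settings = s, seed = 9)
  pw <- b$summary$p_weights_mean
  expect_equal(sum(pw), 1, tolerance = 1e-9)
  expect_lt(max(abs(pw - 1 / 4)), 0.1)
})

test_that("FMA per-vector table carries the interval-derived SDs", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.3, berkson_unshared = 0.2)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 10, seed = 5)
  ft <- fma_fit_all(ens$cohort, ens$doses, "linear-quadratic")
  expect_equal(nrow(ft), 10)
  ok <- ft$usable
  expect_true(any(ok))
  hw <- pmin(ft$alpha[ok] - ft$alo[ok], ft$ahi[ok] - ft$alpha[ok])
  expect_equal(ft$sd_alpha[ok], hw / qnorm(0.975))
  # zero Berkson error: all per-vector fits identical
  ez <- build_ensemble(g, error_config(), risk_model_spec("linear-quadratic"),
                       m = 5, seed = 5)
  fz <- fma_fit_all(ez$cohort, ez$doses, "linear-quadratic")
  expect_equal(max(fz$alpha) - min(fz$alpha), 0)
  expect_equal(max(fz$aic) - min(fz$aic), 0)
})

test_that("default-cohort dose vectors are statistically near-equivalent fits", {
  # with the full-size cohort the within-group averages wash out unshared
  # Berkson noise, so the per-vector fits form a near-scale family and
  # their AICs are nearly identical -- the reason the model-averaged
  # posterior stays broad (see the methods vignette)
  g <- dose_group_spec()
  cfg <- error_config(berkson_unshared = 0.2, berkson_shared = 0.5,
                      classical_shared = 0.2, classical_unshared = 0.2)
  ens <- build_ensemble(g, cfg, risk_model_spec("linear-quadratic"),
                        m = 200, seed = 13)
  ft <- fma_fit_all(ens$cohort, ens$doses, "linear-quadratic")
  expect_lt(diff(range(ft$aic[ft$usable])), 1)
})

test_that("AIC weights are a stabilized softmax with shift invariance", {
  expect_equal(fma_weights(c(0, 2)), c(exp(0), exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(fma_weights(rep(5, 30)), rep(1 / 30, 30))
  a <- runif(20, 10, 40)
  expect_equal(fma_weights(a), fma_weights(a + 123.4), tolerance = 1e-12)
  expect_equal(sum(fma_weights(a)), 1, tolerance = 1e-12)
  expect_error(fma_weights(c(Inf, Inf)), "infinite")
})

test_that("FMA combination matches single-normal and brute-force centile oracles", {
  # m = 1: central estimate -> MLE and CI -> MLE +/- 1.96 SD as k grows
  fits <- data.frame(alpha = 1.7, beta = NA, kappa = -4, loglik = -10,
                     aic = 24, alo = 1.2, ahi = 2.4, sd_alpha = 0.2,
                     sd_beta = NA, usable = TRUE, conv = 1)
  attr(fits, "n_excluded") <- 0L
  f <- fma_combine(fits, 1, k = 1e5, seed = 1, form = "linear")
  expect_equal(f$alpha_hat, 1.7, tolerance = 0.005)
  expect_equal(f$ci_alpha, 1.7 + c(-1, 1) * 1.96 * 0.2, tolerance = 0.01)
  # weighted centile routine against sort-and-accumulate
  set.seed(42)
  x <- rnorm(500); w <- runif(500)
  for (p in c(0.025, 0.5, 0.975)) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    brute <- x[o][which(cw >= p)[1]]
    expect_equal(weighted_quantile(x, w, p), brute)
  }
  # two identical vectors behave like one
  fits2 <- rbind(fits, fits)
  attr(fits2, "n_excluded") <- 0L
  f2 <- fma_combine(fits2, c(0.5, 0.5), k = 1e4, seed = 2, form = "linear")
  f1 <- fma_combine(fits, 1, k = 2e4, seed = 2, form = "linear")
  expect_equal(f2$alpha_hat, f1$alpha_hat, tolerance = 0.01)
})
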