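test_that("error field draws have the contracted shapes and are deterministic", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.5, berkson_unshared = 0.2)
  d1 <- draw_error_fields(50, g, cfg, seed = 3)
  n <- sum(g$n_individuals)
  expect_length(d1$eps, 50)
  expect_length(d1$mu, 50)
  expect_equal(dim(d1$delta), c(50, n))
  expect_equal(dim(d1$kappa_err), c(50, n))
  d2 <- draw_error_fields(50, g, cfg, seed = 3)
  expect_identical(d1, d2)
  expect_error(draw_error_fields(0, g, cfg), "m must be")
})

test_that("error fields are standard normal and come from independent streams", {
  g <- dose_group_spec(n_individuals = c(2, 2, 2, 2, 2),
                       person_years = rep(1, 5))
  cfg <- error_config(berkson_shared = 0.2)
  d <- draw_error_fields(1e5, g, cfg, seed = 1)
  expect_lt(abs(mean(d$eps)), 3 / sqrt(1e5))
  expect_lt(abs(sd(d$eps) - 1), 0.02)
  # changing a classical magnitude never perturbs the Berkson streams
  cfg2 <- error_config(berkson_shared = 0.2, classical_shared = 0.5,
                       classical_unshared = 0.5)
  d2 <- draw_error_fields(100, g, cfg2, seed = 7)
  d1 <- draw_error_fields(100, g, cfg, seed = 7)
  expect_identical(d1$eps, d2$eps)
  expect_identical(d1$delta, d2$delta)
})

test_that("true doses follow the lognormal construction and preserve the mean", {
  g <- small_groups()
  gi <- rep(seq_along(g$n_individuals), g$n_individuals)
  cfg <- error_config(berkson_shared = 0.3, berkson_unshared = 0.4)
  d <- draw_error_fields(20, g, cfg, seed = 5)
  D <- generate_true_doses(g, d, cfg)
  # entry-level identity against a direct evaluation of the product
  j <- 7; i <- 41
  adj <- exp(-0.5 * (0.3^2 + 0.4^2))
  expect_equal(D[j, i],
               g$central_doses[gi[i]] * adj *
                 exp(0.3 * d$eps[j] + 0.4 * d$delta[j, i]))
  # zero Berkson error: every true dose equals its group central estimate
  z <- error_config(classical_shared = 0.5)
  dz <- draw_error_fields(5, g, z, seed = 5)
  Dz <- generate_true_doses(g, dz, z)
  expect_equal(unname(Dz[3, ]), g$central_doses[gi])
  # Monte-Carlo mean matches the central estimate within 1%
  g2 <- dose_group_spec(n_individuals = c(2, 2, 2, 2, 2),
                        person_years = rep(1, 5))
  big <- draw_error_fields(1e5, g2, cfg, seed = 11)
  Dbig <- generate_true_doses(g2, big, cfg)
  expect_lt(max(abs(colMeans(Dbig) / g2$central_doses[rep(1:5, each = 2)] - 1)),
            0.01)
})

test_that("surrogate doses depend only on the classical components", {
  g <- small_groups()
  cfg <- error_config(berkson_shared = 0.5, classical_shared = 0.2,
                      classical_unshared = 0.2)
  d <- draw_error_fields(2000, g, cfg, seed = 2)
  S <- generate_surrogate_doses(g, d, cfg)
  # pure Berkson: surrogate equals the central estimate
  pb <- error_config(berkson_shared = 0.5, berkson_unshared = 0.5)
  dpb <- draw_error_fields(4, g, pb, seed = 2)
  Spb <- generate_surrogate_doses(g, dpb, pb)
  gi <- rep(seq_along(g$n_individuals), g$n_individuals)
  expect_equal(unname(Spb[1, ]), g$central_doses[gi])
  # log(surrogate / central) variance = sum of the two classical variances
  lr <- log(S[, 1] / g$central_doses[1])
  expect_equal(var(lr), 0.08, tolerance = 0.1)
  # Berkson magnitudes do not touch the surrogate matrix
  cfg2 <- error_config(berkson_shared = 0.1, berkson_unshared = 0.4,
                       classical_shared = 0.2, classical_unshared = 0.2)
  d2 <- draw_error_fields(2000, g, cfg2, seed = 2)
  expect_identical(S, generate_surrogate_doses(g, d2, cfg2))
})

test_that("group means collapse correctly", {
  g <- small_groups()
  cfg <- error_config()
  d <- draw_error_fields(3, g, cfg, seed = 1)
  D <- generate_true_doses(g, d, cfg)
  gm <- group_mean_doses(D, g)
  expect_equal(unname(gm[2, ]), g$central_doses)  # zero error degeneracy
  # hand-built two-individual group: mean of 1 and 3 is 2
  g1 <- dose_group_spec(central_doses = c(0.5, 2), n_individuals = c(2, 2),
                        person_years = c(1, 1), bounds = c("a", "b"))
  Dm <- matrix(c(1, 3, 5, 7), nrow = 1)
  expect_equal(unname(group_mean_doses(Dm, g1)[1, ]), c(2, 6))
})

test_that("dose correlation matches shared-error degeneracies and the lognormal formula", {
  g <- small_groups()
  # pure shared Berkson error: correlation exactly 1
  sh <- error_config(berkson_shared = 0.5)
  d <- draw_error_fields(200, g, sh, seed = 4)
  D <- generate_true_doses(g, d, sh)
  expect_equal(dose_correlation(D), 1, tolerance = 1e-10)
  # mixed shared/unshared: matches (e^{s^2}-1)/(e^{s^2+u^2}-1)
  for (su in list(c(0.2, 0.2), c(0.5, 0.2), c(0.2, 0.5))) {
    cfg <- error_config(berkson_shared = su[1], berkson_unshared = su[2])
    dd <- draw_error_fields(1000, g, cfg, seed = 8)
    DD <- generate_true_doses(g, dd, cfg)
    expect_equal(dose_correlation(DD, seed = 8),
                 analytic_dose_correlation(cfg), tolerance = 0.03)
  }
  expect_equal(analytic_dose_correlation(
    error_config(berkson_shared = 0.2, berkson_unshared = 0.2)),
    0.490, tolerance = 5e-4)
  expect_true(is.na(analytic_dose_correlation(error_config())))
})
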