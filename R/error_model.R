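#' Error-magnitude configuration
#'
#' The four log-scale standard deviations (geometric standard deviations,
#' GSDs) of the composite Berkson-classical lognormal dose error model:
#' shared and unshared Berkson components act on the true dose, shared and
#' unshared classical components act on the surrogate (observed) dose.
#' A value of 0.2 corresponds to "20% error" in the usual GSD shorthand.
#'
#' @param berkson_shared,berkson_unshared,classical_shared,classical_unshared
#'   non-negative log-scale SDs (dimensionless).
#' @return an object of class `doserr_error_config`.
#' @export
#' @examples
#' error_config(berkson_shared = 0.5, berkson_unshared = 0.2,
#'              classical_shared = 0.2, classical_unshared = 0.2)
error_config <- function(berkson_shared = 0, berkson_unshared = 0,
                         classical_shared = 0, classical_unshared = 0) {
  v <- c(berkson_shared = berkson_shared, berkson_unshared = berkson_unshared,
         classical_shared = classical_shared,
         classical_unshared = classical_unshared)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all error magnitudes must be finite and >= 0")
  }
  structure(as.list(v), class = "doserr_error_config")
}

#' @export
print.doserr_error_config <- function(x, ...) {
  cat(sprintf(
    "<error config> Berkson shared/unshared: %g/%g  classical shared/unshared: %g/%g\n",
    x$berkson_shared, x$berkson_unshared,
    x$classical_shared, x$classical_unshared))
  invisible(x)
}

#' Dose-group specification
#'
#' The grouped cohort skeleton: dose-group boundaries, the central dose
#' estimate assigned to each group, person-year offsets and the number of
#' individuals per group. Defaults follow the Life Span Study leukaemia
#' bone-marrow dose grouping (0-0.07, 0.08-0.19, 0.20-0.99, 1.00-2.49 and
#' 2.50+ Gy) with a central estimate of 2 Gy in the uppermost group; the
#' remaining central doses and the low-dose-heavy person-year distribution
#' are documented package defaults (see the methods vignette) and fully
#' configurable.
#'
#' @param central_doses central dose estimate per group (Gy), strictly
#'   increasing and positive.
#' @param n_individuals individuals per group (each >= 2); default
#'   apportions `n_total` as 70/15/10/4/1 percent.
#' @param person_years person-year offset per group (arbitrary units);
#'   default proportional to `n_individuals`.
#' @param n_total total cohort size used to build the default
#'   `n_individuals`.
#' @param bounds character labels for the group dose intervals.
#' @return an object of class `doserr_groups`.
#' @export
#' @examples
#' dose_group_spec()
dose_group_spec <- function(central_doses = c(0.03, 0.12, 0.50, 1.50, 2.00),
                            n_individuals = NULL,
                            person_years = NULL,
                            n_total = 10000,
                            bounds = c("0-0.07", "0.08-0.19", "0.20-0.99",
                                       "1.00-2.49", ">=2.50")) {
  ng <- length(central_doses)
  if (is.null(n_individuals)) {
    if (ng != 5) stop("default n_individuals requires 5 groups")
    n_individuals <- round(c(0.70, 0.15, 0.10, 0.04, 0.01) * n_total)
  }
  if (is.null(person_years)) person_years <- as.numeric(n_individuals)
  if (length(bounds) != ng) bounds <- paste0("group", seq_len(ng))
  if (any(central_doses <= 0) || any(diff(central_doses) <= 0)) {
    stop("central_doses must be positive and strictly increasing")
  }
  if (length(n_individuals) != ng || length(person_years) != ng) {
    stop("central_doses, n_individuals and person_years must have equal length")
  }
  if (any(n_individuals < 2)) stop("need >= 2 individuals per group")
  if (any(person_years <= 0)) stop("person_years must be > 0")
  structure(list(bounds = bounds,
                 central_doses = as.numeric(central_doses),
                 person_years = as.numeric(person_years),
                 n_individuals = as.integer(n_individuals)),
            class = "doserr_groups")
}

#' @export
print.doserr_groups <- function(x, ...) {
  cat("<dose groups>\n")
  print(data.frame(bounds = x$bounds, central_dose_Gy = x$central_doses,
                   person_years = x$person_years,
                   n_individuals = x$n_individuals), row.names = FALSE)
  invisible(x)
}

# group membership index (one entry per individual)
group_index <- function(groups) {
  rep(seq_along(groups$n_individuals), groups$n_individuals)
}

#' Draw the four standard-normal error fields
#'
#' Draws the shared Berkson (`eps`), shared classical (`mu`), unshared
#' Berkson (`delta`) and unshared classical (`kappa_err`) standard-normal
#' fields for `m` sub-simulations of a cohort. Each field comes from its own
#' random-number stream derived from the master seed, so that changing one
#' error magnitude never perturbs the draws feeding the other components.
#' The unshared fields are `m x n` matrices (sub-simulation by individual)
#' whose row `j` is a contiguous prefix of the stream, so that partial
#' generation of early sub-simulations is reproducible.
#'
#' @param m number of sub-simulations (>= 1).
#' @param groups a [dose_group_spec()].
#' @param config an [error_config()] (carried for provenance; the draws
#'   themselves are sigma-free standard normals).
#' @param seed master integer seed.
#' @return an object of class `doserr_error_draws` with elements `eps`,
#'   `mu` (length `m`), `delta`, `kappa_err` (`m x n` matrices), `m`, `n`.
#' @export
draw_error_fields <- function(m, groups, config, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  n <- sum(groups$n_individuals)
  eps <- with_seed(derive_seed(seed, "eps"), rnorm(m))
  mu <- with_seed(derive_seed(seed, "mu"), rnorm(m))
  delta <- with_seed(derive_seed(seed, "delta"),
                     matrix(rnorm(as.numeric(m) * n), nrow = m, byrow = TRUE))
  kappa_err <- with_seed(derive_seed(seed, "kappa_err"),
                         matrix(rnorm(as.numeric(m) * n), nrow = m,
                                byrow = TRUE))
  structure(list(eps = eps, mu = mu, delta = delta, kappa_err = kappa_err,
                 m = m, n = n, seed = as.integer(seed)),
            class = "doserr_error_draws")
}

check_draw_shape <- function(draws, groups) {
  n <- sum(groups$n_individuals)
  if (draws$n != n || ncol(draws$delta) != n || ncol(draws$kappa_err) != n ||
      nrow(draws$delta) != draws$m || length(draws$eps) != draws$m) {
    stop("error draws do not match the dose-group specification")
  }
  invisible(TRUE)
}

# shared machinery for the two lognormal dose constructions
lognormal_doses <- function(groups, shared_draw, unshared_draw,
                            sigma_shared, sigma_unshared) {
  gi <- group_index(groups)
  adj <- exp(-0.5 * (sigma_shared^2 + sigma_unshared^2))
  d <- exp(sigma_unshared * unshared_draw + sigma_shared * shared_draw)
  sweep(d, 2, groups$central_doses[gi] * adj, "*")
}

#' Generate true doses under the Berkson error components
#'
#' True dose for individual `i` of group `k` in sub-simulation `j` is the
#' group central estimate times
#' `exp(-(s^2 + u^2)/2) * exp(s * eps_j + u * delta_ij)` with `s`, `u` the
#' shared and unshared Berkson log-scale SDs, so that the theoretical mean
#' coincides with the central estimate. Independent of the classical error
#' magnitudes.
#'
#' @param groups a [dose_group_spec()].
#' @param draws a [draw_error_fields()] result.
#' @param config an [error_config()].
#' @return an `m x n` matrix of doses (Gy), sub-simulation by individual.
#' @export
generate_true_doses <- function(groups, draws, config) {
  check_draw_shape(draws, groups)
  lognormal_doses(groups, draws$eps, draws$delta,
                  config$berkson_shared, config$berkson_unshared)
}

#' Generate surrogate doses under the classical error components
#'
#' Surrogate (observed) dose, built like [generate_true_doses()] but from
#' the shared (`mu`) and unshared (`kappa_err`) classical fields; the
#' Berkson magnitudes play no role.
#'
#' @inheritParams generate_true_doses
#' @return an `m x n` matrix of doses (Gy).
#' @export
generate_surrogate_doses <- function(groups, draws, config) {
  check_draw_shape(draws, groups)
  lognormal_doses(groups, draws$mu, draws$kappa_err,
                  config$classical_shared, config$classical_unshared)
}

#' Per-group mean doses
#'
#' Collapses an `m x n` individual dose matrix to the `m x G` matrix of
#' arithmetic group means used by the grouped estimators.
#'
#' @param doses `m x n` dose matrix.
#' @param groups a [dose_group_spec()].
#' @return an `m x G` matrix of group-mean doses (Gy).
#' @export
group_mean_doses <- function(doses, groups) {
  n <- sum(groups$n_individuals)
  if (ncol(doses) != n) stop("dose matrix does not match groups")
  gi <- group_index(groups)
  w <- vapply(seq_along(groups$n_individuals),
              function(g) as.numeric(gi == g) / groups$n_individuals[g],
              numeric(n))
  doses %*% w
}

#' Average between-individual dose correlation
#'
#' The sample Pearson correlation between two individuals' dose series
#' across sub-simulations, averaged over randomly sampled distinct pairs
#' (all pairs when few). Shared error components drive this correlation
#' towards 1, unshared components towards 0; see
#' [analytic_dose_correlation()] for the closed-form lognormal value.
#'
#' Degenerate (constant) series arise only when both error components are
#' zero; a pair of identical constant series is scored 1 (pure shared
#' scaling), any other constant pair is excluded with a warning.
#'
#' @param doses `m x n` dose matrix with `m >= 3`, `n >= 2`.
#' @param max_pairs maximum number of sampled pairs (default 500).
#' @param seed seed for pair sampling.
#' @return average pairwise correlation in `[-1, 1]` (`NaN` if every pair
#'   was excluded).
#' @export
dose_correlation <- function(doses, max_pairs = 500, seed = 1L) {
  m <- nrow(doses); n <- ncol(doses)
  if (m < 3) stop("need >= 3 sub-simulations")
  if (n < 2) stop("need >= 2 individuals")
  if (choose(n, 2) <= max_pairs) {
    pairs <- t(utils::combn(n, 2))
  } else {
    pairs <- with_seed(derive_seed(seed, "corr-pairs"), {
      got <- matrix(integer(0), ncol = 2)
      while (nrow(got) < max_pairs) {
        cand <- matrix(sample.int(n, 4 * max_pairs, replace = TRUE), ncol = 2)
        cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
        cand <- t(apply(cand, 1, sort))
        got <- unique(rbind(got, cand))
      }
      got[seq_len(max_pairs), , drop = FALSE]
    })
  }
  vals <- numeric(0)
  dropped <- 0L
  for (r in seq_len(nrow(pairs))) {
    s1 <- doses[, pairs[r, 1]]
    s2 <- doses[, pairs[r, 2]]
    v1 <- stats::sd(s1); v2 <- stats::sd(s2)
    if (v1 == 0 || v2 == 0) {
      if (v1 == 0 && v2 == 0 && isTRUE(all.equal(s1, s2))) {
        vals <- c(vals, 1)
      } else {
        dropped <- dropped + 1L
      }
    } else {
      vals <- c(vals, cor(s1, s2))
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d constant, non-identical pairs excluded", dropped))
  }
  mean(vals)
}

#' Closed-form between-individual dose correlation
#'
#' For the lognormal error model the correlation between two individuals'
#' doses is `(exp(s^2) - 1) / (exp(s^2 + u^2) - 1)` with `s` the shared and
#' `u` the unshared log-scale SD. Returns `NA` when both are zero (the
#' doses are then constant and the correlation is undefined).
#'
#' @param config an [error_config()]; the Berkson components are used.
#' @return correlation in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' analytic_dose_correlation(error_config(berkson_shared = 0.5,
#'                                        berkson_unshared = 0.2))
analytic_dose_correlation <- function(config) {
  s <- config$berkson_shared
  u <- config$berkson_unshared
  if (s == 0 && u == 0) return(NA_real_)
  if (u == 0) return(1)
  (exp(s^2) - 1) / (exp(s^2 + u^2) - 1)
}
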