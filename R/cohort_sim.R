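#' Risk-model specification
#'
#' The excess-relative-risk dose response `RR(d) = 1 + alpha d + beta d^2`.
#' Defaults are the stratified fits to Life Span Study leukaemia data used
#' throughout the simulation study: linear-quadratic `alpha = 0.25`/Gy,
#' `beta = 2`/Gy^2; linear `alpha = 3`/Gy.
#'
#' @param form `"linear-quadratic"` or `"linear"` (linear forces
#'   `beta = 0`).
#' @param alpha linear ERR coefficient (per Gy).
#' @param beta quadratic ERR coefficient (per Gy^2).
#' @return an object of class `doserr_risk`.
#' @export
#' @examples
#' risk_model_spec("linear-quadratic")
#' risk_model_spec("linear")
risk_model_spec <- function(form = c("linear-quadratic", "linear"),
                            alpha = NULL, beta = NULL) {
  form <- match.arg(form)
  if (form == "linear") {
    if (is.null(alpha)) alpha <- 3
    if (!is.null(beta) && beta != 0) stop("linear form requires beta = 0")
    beta <- 0
  } else {
    if (is.null(alpha)) alpha <- 0.25
    if (is.null(beta)) beta <- 2
  }
  structure(list(form = form, alpha = alpha, beta = beta),
            class = "doserr_risk")
}

#' @export
print.doserr_risk <- function(x, ...) {
  cat(sprintf("<risk model> %s: alpha = %g /Gy, beta = %g /Gy^2\n",
              x$form, x$alpha, x$beta))
  invisible(x)
}

#' Grouped cohort of cases and offsets
#'
#' The unit every estimator consumes: one case count and one person-year
#' offset per dose group.
#'
#' @param cases non-negative integer case count per group.
#' @param person_years positive person-year offset per group.
#' @return an object of class `doserr_cohort` with `cases`, `person_years`
#'   and `n_total_cases`.
#' @export
grouped_cohort <- function(cases, person_years) {
  cases <- as.integer(cases)
  if (length(cases) != length(person_years)) stop("length mismatch")
  if (any(cases < 0)) stop("cases must be >= 0")
  if (any(person_years <= 0)) stop("person_years must be > 0")
  structure(list(cases = cases, person_years = as.numeric(person_years),
                 n_total_cases = sum(cases)),
            class = "doserr_cohort")
}

#' @export
print.doserr_cohort <- function(x, ...) {
  cat(sprintf("<grouped cohort> %d cases over %d groups\n",
              x$n_total_cases, length(x$cases)))
  print(data.frame(cases = x$cases, person_years = x$person_years),
        row.names = FALSE)
  invisible(x)
}

# per-individual sampling weights: uniform within group, group totals
# proportional to person-years
individual_weights <- function(groups) {
  gi <- group_index(groups)
  w <- (groups$person_years / groups$n_individuals)[gi]
  w / sum(w)
}

#' Per-individual mean relative risk over sub-simulations
#'
#' Individual `i` receives the average over sub-simulations `j` of
#' `1 + alpha D_ij + beta D_ij^2`, i.e. the expectation of the relative
#' risk over the dose ensemble.
#'
#' @param true_doses `m x n` matrix of true doses (Gy).
#' @param risk a [risk_model_spec()].
#' @return numeric vector of length `n`, all values > 0.
#' @export
mean_relative_risks <- function(true_doses, risk) {
  rr <- 1 + risk$alpha * colMeans(true_doses) +
    risk$beta * colMeans(true_doses^2)
  if (any(rr <= 1e-12)) {
    stop("risk model yields non-positive relative risks over the dose support")
  }
  rr
}

#' Normalizing constant for the case-probability model
#'
#' Returns `kappa` (log scale) such that
#' `exp(kappa) * sum(weights * mean_rr) = 1`.
#'
#' @param mean_rr positive per-individual mean relative risks.
#' @param weights per-individual weights.
#' @return scalar `kappa`.
#' @export
normalizing_constant <- function(mean_rr, weights) {
  if (!length(mean_rr)) stop("empty input")
  if (any(mean_rr <= 0)) stop("mean relative risks must be > 0")
  -log(sum(weights * mean_rr))
}

#' Simulate the grouped distribution of cancer cases
#'
#' Draws `N` cases from the multinomial over dose groups whose group
#' probability is proportional to the person-year-weighted sum of the
#' individual mean relative risks within the group.
#'
#' @param mean_rr per-individual mean relative risks
#'   ([mean_relative_risks()]).
#' @param groups a [dose_group_spec()].
#' @param N total number of cases (default 250).
#' @param seed integer seed for the multinomial draw.
#' @return a [grouped_cohort()] whose cases sum to `N`.
#' @export
simulate_cases <- function(mean_rr, groups, N = 250, seed = 1L) {
  if (N < 1) stop("N must be >= 1")
  gi <- group_index(groups)
  w <- individual_weights(groups)
  p <- as.numeric(rowsum(w * mean_rr, gi))
  if (all(p == 0)) stop("all group probabilities are zero")
  p <- p / sum(p)
  y <- with_seed(derive_seed(seed, "cases"),
                 as.integer(rmultinom(1, N, p)))
  grouped_cohort(y, groups$person_years)
}

#' Set of per-group dose vectors
#'
#' The `m` per-group dose realizations retained for Monte Carlo maximum
#' likelihood, Bayesian and frequentist model averaging, together with
#' their across-realization mean (the regression-calibration dose vector).
#'
#' @param vectors `m x G` matrix of per-group doses (Gy), all entries > 0.
#' @return an object of class `doserr_dose_set` with `vectors`,
#'   `mean_vector` and `m`.
#' @export
dose_vector_set <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (any(vectors <= 0)) stop("dose vectors must be positive")
  structure(list(vectors = vectors,
                 mean_vector = colMeans(vectors),
                 m = nrow(vectors)),
            class = "doserr_dose_set")
}

#' @export
print.doserr_dose_set <- function(x, ...) {
  cat(sprintf("<dose vector set> m = %d realizations of %d groups\n",
              x$m, ncol(x$vectors)))
  cat("mean vector (Gy):", signif(x$mean_vector, 4), "\n")
  invisible(x)
}

#' Collapse individual doses and cases to the grouped representation
#'
#' Sums cases and averages doses into the dose groups: per-sub-simulation
#' group-mean dose vectors are retained (for MCML and the model-averaging
#' methods) along with their across-realization mean (for regression
#' calibration).
#'
#' @param true_doses `m x n` matrix of true doses.
#' @param cases a [grouped_cohort()] (already grouped; passed through).
#' @param groups a [dose_group_spec()].
#' @return list with `cohort` and `doses` (a [dose_vector_set()]).
#' @export
collapse_to_groups <- function(true_doses, cases, groups) {
  list(cohort = cases,
       doses = dose_vector_set(group_mean_doses(true_doses, groups)))
}

#' Build one dose + cancer meta-simulation ensemble
#'
#' Composes the full generative pipeline for one meta-simulation: draws the
#' four error fields, forms `m` sub-simulated true-dose realizations,
#' computes the per-individual mean relative risks, simulates the grouped
#' distribution of `n_cases` cancers (held constant across the `m`
#' sub-simulations), and collapses to the per-group dose vectors the
#' estimators consume. The designated dose vector for unadjusted regression
#' is the first sub-simulation's surrogate group means (averaging surrogate
#' doses over sub-simulations would cancel the shared classical error).
#'
#' Zero-magnitude error components are skipped without consuming
#' random-number draws; this is exactly reproducible because each field has
#' its own stream (see [draw_error_fields()]).
#'
#' @param groups a [dose_group_spec()].
#' @param config an [error_config()].
#' @param risk a [risk_model_spec()].
#' @param m number of sub-simulations (default 1000).
#' @param n_cases total cases `N` (default 250).
#' @param seed master integer seed for the ensemble.
#' @param keep_individual keep the full `m x n` individual dose matrices
#'   (memory-heavy; default `FALSE`).
#' @return an object of class `doserr_ensemble` with elements `cohort`,
#'   `doses` (true-dose [dose_vector_set()]), `unadjusted_doses`
#'   (per-group surrogate vector), `kappa_sim`, and the generating
#'   specification.
#' @export
build_ensemble <- function(groups, config, risk, m = 1000, n_cases = 250,
                           seed = 1L, keep_individual = FALSE) {
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  n <- sum(groups$n_individuals)
  gi <- group_index(groups)
  ngrp <- length(groups$central_doses)
  cd <- groups$central_doses

  eps <- with_seed(derive_seed(seed, "eps"), rnorm(m))
  mu <- with_seed(derive_seed(seed, "mu"), rnorm(m))

  sb <- config$berkson_shared; ub <- config$berkson_unshared
  adj_b <- exp(-0.5 * (sb^2 + ub^2))
  sh_b <- exp(sb * eps)

  # group-membership averaging matrix (n x G)
  W <- vapply(seq_len(ngrp),
              function(g) as.numeric(gi == g) / groups$n_individuals[g],
              numeric(n))

  ind_true <- NULL
  if (ub > 0) {
    # individual-by-sub-simulation orientation (n x m): column j is the
    # contiguous j-th block of the stream, matching draw_error_fields()
    delta <- with_seed(derive_seed(seed, "delta"),
                       matrix(rnorm(as.numeric(m) * n), nrow = n))
    dmat <- (cd[gi] * adj_b) * exp(ub * delta)
    rm(delta)
    dmat <- dmat * rep(sh_b, each = n)
    gm_true <- crossprod(dmat, W)          # m x G group means of dose
    gm_true2 <- crossprod(dmat * dmat, W)  # m x G group means of dose^2
    if (keep_individual) ind_true <- t(dmat)
    rm(dmat)
  } else {
    gm_true <- outer(sh_b, cd * adj_b)
    gm_true2 <- gm_true^2
    if (keep_individual) ind_true <- gm_true[, gi, drop = FALSE]
  }

  # grouped mean relative risks (identical arithmetic to averaging the
  # per-individual mean RR within groups, since weights are uniform there)
  rr_g <- 1 + risk$alpha * colMeans(gm_true) + risk$beta * colMeans(gm_true2)
  if (any(rr_g <= 1e-12)) {
    stop("risk model yields non-positive relative risks over the dose support")
  }
  py_frac <- groups$person_years / sum(groups$person_years)
  kappa_sim <- -log(sum(py_frac * rr_g))
  p <- py_frac * rr_g
  p <- p / sum(p)
  y <- with_seed(derive_seed(seed, "cases"),
                 as.integer(rmultinom(1, n_cases, p)))
  cohort <- grouped_cohort(y, groups$person_years)

  # designated unadjusted dose vector: sub-simulation 1 surrogate group means
  sc <- config$classical_shared; uc <- config$classical_unshared
  adj_c <- exp(-0.5 * (sc^2 + uc^2))
  if (uc > 0) {
    krow <- with_seed(derive_seed(seed, "kappa_err"), rnorm(n))
    surr1 <- cd[gi] * adj_c * exp(uc * krow) * exp(sc * mu[1])
    unadj <- as.numeric(crossprod(surr1, W))
  } else {
    unadj <- cd * adj_c * exp(sc * mu[1])
  }

  structure(list(cohort = cohort,
                 doses = dose_vector_set(gm_true),
                 unadjusted_doses = unadj,
                 kappa_sim = kappa_sim,
                 groups = groups, config = config, risk = risk,
                 m = m, n_cases = as.integer(n_cases),
                 seed = as.integer(seed),
                 individual_true_doses = ind_true),
            class = "doserr_ensemble")
}

#' @export
print.doserr_ensemble <- function(x, ...) {
  cat(sprintf(
    "<meta-simulation ensemble> m = %d sub-simulations, N = %d cases, seed %d\n",
    x$m, x$n_cases, x$seed))
  print(x$config)
  print(x$cohort)
  invisible(x)
}
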