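#' Unadjusted regression on the surrogate dose
#'
#' Fits the grouped relative-risk model to the ensemble's designated
#' surrogate dose vector (the only estimator that sees the surrogate dose,
#' and hence the only one affected by classical error).
#'
#' @param cohort a [grouped_cohort()].
#' @param ensemble a [build_ensemble()] result carrying
#'   `unadjusted_doses`.
#' @param form `"linear-quadratic"` or `"linear"`.
#' @param level confidence level.
#' @return a `doserr_fit` with method tag `"unadjusted"`.
#' @export
fit_unadjusted <- function(cohort, ensemble,
                           form = c("linear-quadratic", "linear"),
                           level = 0.95) {
  form <- match.arg(form)
  fit_mle(cohort, ensemble$unadjusted_doses, form, level = level,
          method = "unadjusted")
}

#' Regression calibration
#'
#' Substitutes the conditional expectation of the true dose — here the
#' across-realization mean of the per-group true-dose vectors — and fits
#' the grouped model to it.
#'
#' @param cohort a [grouped_cohort()].
#' @param doses a [dose_vector_set()].
#' @inheritParams fit_unadjusted
#' @return a `doserr_fit` with method tag `"regression_calibration"`.
#' @export
fit_regression_calibration <- function(cohort, doses,
                                       form = c("linear-quadratic", "linear"),
                                       level = 0.95) {
  form <- match.arg(form)
  fit_mle(cohort, doses$mean_vector, form, level = level,
          method = "regression_calibration")
}

#' Extended regression calibration (shared-error-aware interval)
#'
#' Point estimates equal the regression-calibration fit's. The confidence
#' interval additionally accounts for shared dose uncertainty: each dose
#' realization is refitted, the between-realization variance of the
#' coefficient is combined with the within-fit profile variance by the law
#' of total variance, and the profile interval is inflated symmetrically by
#' the resulting factor. With no Berkson error all realizations coincide,
#' the between-realization variance is zero and the method reduces exactly
#' to regression calibration; with a single realization the inflation step
#' is skipped and flagged.
#'
#' @inheritParams fit_regression_calibration
#' @return a `doserr_fit` with method tag `"erc"`.
#' @export
fit_erc <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                    level = 0.95) {
  form <- match.arg(form)
  rc <- fit_mle(cohort, doses$mean_vector, form, level = level,
                method = "erc")
  if (doses$m == 1) {
    rc$diagnostics$inflation <- "skipped (single dose realization)"
    return(rc)
  }
  q <- qchisq(level, df = 1)
  refits <- cpp_fit_batch(as.numeric(cohort$cases), cohort$person_years,
                          doses$vectors, form == "linear", q, FALSE)
  ok <- refits[, "conv"] > 0.5
  z <- qnorm(1 - (1 - level) / 2)
  inflate <- function(ci, est, between_var) {
    if (is.null(ci) || any(!is.finite(ci))) return(ci)
    sd_w <- (ci[2] - ci[1]) / (2 * z)
    if (sd_w <= 0) return(ci)
    f <- sqrt(1 + between_var / sd_w^2)
    est + (ci - est) * f
  }
  var_a <- var(refits[ok, "alpha"])
  rc$ci_alpha <- inflate(rc$ci_alpha, rc$alpha_hat, var_a)
  if (form != "linear") {
    var_b <- var(refits[ok, "beta"])
    rc$ci_beta <- inflate(rc$ci_beta, rc$beta_hat, var_b)
  }
  rc$diagnostics$n_refits_used <- sum(ok)
  rc$diagnostics$between_var_alpha <- var_a
  if (form != "linear") rc$diagnostics$between_var_beta <- var(refits[ok, "beta"])
  rc
}

# Monte-Carlo-averaged log-likelihood: log[(1/m) sum_k L_k(theta)],
# vectorized over the m dose vectors
mcml_objective <- function(theta, cohort, D, linear, const) {
  a <- theta[1]
  b <- if (linear) 0 else theta[2]
  k <- theta[[length(theta)]]
  r <- 1 + a * D + b * D * D
  bad <- rowSums(r <= 0) > 0
  y <- cohort$cases
  off <- cohort$person_years
  ll <- const + cohort$n_total_cases * k +
    (log(pmax(r, 1e-300)) %*% y) - exp(k) * (r %*% off)
  ll[bad] <- -Inf
  logsumexp(as.numeric(ll)) - log(nrow(D))
}

#' Monte Carlo maximum likelihood
#'
#' Maximizes the Monte-Carlo likelihood `(1/m) sum_k L_k(theta)` — the
#' average over the `m` dose realizations of the grouped Poisson likelihood
#' (average of likelihoods, not of log-likelihoods) — and derives profile
#' confidence intervals on the same averaged likelihood.
#'
#' @inheritParams fit_regression_calibration
#' @return a `doserr_fit` with method tag `"mcml"`.
#' @export
fit_mcml <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                     level = 0.95) {
  form <- match.arg(form)
  linear <- form == "linear"
  D <- doses$vectors
  y <- cohort$cases
  const <- sum(y * log(cohort$person_years)) - sum(lgamma(y + 1))

  start_fit <- fit_mle(cohort, doses$mean_vector, form, ci = FALSE)
  start <- if (linear) c(start_fit$alpha_hat, start_fit$kappa_hat)
           else c(start_fit$alpha_hat, start_fit$beta_hat,
                  start_fit$kappa_hat)
  obj <- function(th) -mcml_objective(th, cohort, D, linear, const)
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  polish <- suppressWarnings(
    try(optim(opt$par, obj, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 500)), silent = TRUE))
  if (!inherits(polish, "try-error") && is.finite(polish$value) &&
      polish$value <= opt$value) {
    opt <- polish
  }
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-13, maxit = 2000))
  if (opt2$value <= opt$value) opt <- opt2
  llhat <- -opt$value
  a <- opt$par[1]
  b <- if (linear) NA_real_ else opt$par[2]
  k <- opt$par[[length(opt$par)]]
  conv <- is.finite(llhat)

  prof <- function(which, val) {
    # maximize over the remaining parameters at a fixed coefficient value
    if (linear) {
      o <- optimize(function(kk)
        mcml_objective(c(val, kk), cohort, D, TRUE, const),
        interval = k + c(-15, 15), maximum = TRUE, tol = 1e-9)
      return(o$objective)
    }
    st <- if (which == "alpha") c(b, k) else c(a, k)
    f <- function(p) {
      th <- if (which == "alpha") c(val, p[1], p[2]) else c(p[1], val, p[2])
      -mcml_objective(th, cohort, D, FALSE, const)
    }
    if (!is.finite(f(st))) {
      # move the nuisance coefficient inside the positivity region of the
      # least-restrictive dose vector
      st[1] <- if (which == "alpha") {
        min(apply(D, 1, function(dv) max(-(1 + val * dv) / dv^2))) + 1
      } else {
        min(apply(D, 1, function(dv) max(-(1 + val * dv^2) / dv))) + 1
      }
    }
    if (!is.finite(f(st))) return(-Inf)
    o <- optim(st, f, method = "Nelder-Mead",
               control = list(reltol = 1e-11, maxit = 3000))
    -o$value
  }
  ci_for <- function(which, est) {
    q <- qchisq(level, df = 1)
    target <- llhat - q / 2
    endpoint <- function(dir) {
      step <- max(0.25, 0.5 * abs(est))
      x <- est
      for (i in 1:60) {
        x2 <- x + dir * step
        if (prof(which, x2) < target) {
          lo <- min(x, x2); hi <- max(x, x2)
          for (j in 1:60) {
            mid <- (lo + hi) / 2
            if ((prof(which, mid) >= target) == (dir > 0)) lo <- mid
            else hi <- mid
            if (hi - lo < 1e-7 * (1 + abs(mid))) break
          }
          return((lo + hi) / 2)
        }
        x <- x2
        step <- step * 1.7
        if (abs(x) > 1e6) return(dir * Inf)
      }
      dir * Inf
    }
    c(endpoint(-1), endpoint(1))
  }
  ci_a <- ci_for("alpha", a)
  ci_b <- if (linear) NULL else ci_for("beta", b)
  fit_result("mcml", form, a, b, k, llhat, ci_alpha = ci_a, ci_beta = ci_b,
             converged = conv,
             diagnostics = list(optim_convergence = opt$convergence))
}
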