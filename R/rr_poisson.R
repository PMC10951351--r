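#' Grouped Poisson linear relative-risk log-likelihood
#'
#' Log-likelihood of grouped case counts under rates
#' `lambda_g = offset_g * exp(kappa) * (1 + alpha d_g + beta d_g^2)`.
#' The constant convention is the full Poisson log-density including the
#' `-log(y!)` terms (so values agree with `dpois(..., log = TRUE)`); the
#' convention is irrelevant to estimates, profile intervals and AIC
#' differences. Returns `-Inf` (not an error) when the relative risk is
#' non-positive in any group, so optimizers and samplers can reject.
#'
#' @param alpha,beta,kappa model parameters.
#' @param cohort a [grouped_cohort()].
#' @param doses per-group dose vector (Gy).
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
rr_loglik <- function(alpha, beta, kappa, cohort, doses) {
  r <- 1 + alpha * doses + beta * doses^2
  if (any(r <= 0)) return(-Inf)
  lam <- cohort$person_years * exp(kappa) * r
  sum(dpois(cohort$cases, lam, log = TRUE))
}

npar_for <- function(form) if (form == "linear") 2L else 3L

fit_result <- function(method, form, alpha, beta, kappa, loglik,
                       ci_alpha = NULL, ci_beta = NULL, converged = TRUE,
                       diagnostics = list()) {
  npar <- npar_for(form)
  structure(list(method = method, form = form,
                 alpha_hat = alpha,
                 beta_hat = if (form == "linear") NA_real_ else beta,
                 kappa_hat = kappa,
                 loglik = loglik,
                 aic = if (is.finite(loglik)) -2 * loglik + 2 * npar
                       else NA_real_,
                 npar = npar,
                 ci_alpha = ci_alpha, ci_beta = ci_beta,
                 converged = converged, diagnostics = diagnostics),
            class = "doserr_fit")
}

#' @export
print.doserr_fit <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (is.null(ci)) return("")
    sprintf(" (%.4g, %.4g)", ci[1], ci[2])
  }
  cat(sprintf("<%s fit, %s>%s\n", x$method, x$form,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  alpha = %.4g%s\n", x$alpha_hat, fmt_ci(x$ci_alpha)))
  if (x$form != "linear") {
    cat(sprintf("  beta  = %.4g%s\n", x$beta_hat, fmt_ci(x$ci_beta)))
  }
  cat(sprintf("  kappa = %.4g   loglik = %.4g   AIC = %.4g\n",
              x$kappa_hat, x$loglik, x$aic))
  invisible(x)
}

ci_flags <- function(flo, fhi) {
  lab <- c("ok", "open", "boundary")
  c(lower = lab[flo + 1], upper = lab[fhi + 1])
}

#' Maximum-likelihood fit of the grouped relative-risk model
#'
#' Maximizes [rr_loglik()] over `(alpha, beta, kappa)` subject to the
#' positivity constraint on the relative risk. `kappa` is profiled out in
#' closed form and the remaining coefficients are maximized by damped
#' Newton iteration with analytic derivatives, multi-start, and a
#' golden-section fallback (deterministic given the inputs).
#'
#' @param cohort a [grouped_cohort()].
#' @param doses per-group dose vector (Gy).
#' @param form `"linear-quadratic"` or `"linear"`.
#' @param ci also compute profile-likelihood confidence intervals
#'   (default `TRUE`).
#' @param level confidence level for the profile intervals.
#' @param method method tag recorded in the result.
#' @return a `doserr_fit` with estimates, log-likelihood, AIC and (if
#'   requested) profile confidence intervals.
#' @export
fit_mle <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                    ci = TRUE, level = 0.95, method = "mle") {
  form <- match.arg(form)
  doses <- as.numeric(doses)
  if (length(doses) != length(cohort$cases)) stop("dose/cohort length mismatch")
  if (cohort$n_total_cases < 1) stop("cohort has no cases")
  q <- qchisq(level, df = 1)
  res <- cpp_fit_batch(as.numeric(cohort$cases), cohort$person_years,
                       matrix(doses, nrow = 1), form == "linear", q, ci)
  r <- res[1, ]
  conv <- r[["conv"]] > 0.5
  diag <- list()
  ci_a <- ci_b <- NULL
  if (ci) {
    ci_a <- c(r[["alo"]], r[["ahi"]])
    diag$ci_alpha_flags <- ci_flags(r[["aflo"]], r[["afhi"]])
    if (form != "linear") {
      ci_b <- c(r[["blo"]], r[["bhi"]])
      diag$ci_beta_flags <- ci_flags(r[["bflo"]], r[["bfhi"]])
    }
  }
  if (!conv) diag$reason <- "optimizer did not reach gradient tolerance"
  fit_result(method, form, r[["alpha"]], r[["beta"]], r[["kappa"]],
             r[["loglik"]], ci_alpha = ci_a, ci_beta = ci_b,
             converged = conv, diagnostics = diag)
}

#' Profile-likelihood confidence interval
#'
#' Endpoints where the profile deviance rises by the chi-square(1)
#' quantile (3.841 at 95%) above its minimum, found by monotone bisection
#' on each side of the maximum-likelihood estimate. A side whose deviance
#' never reaches the threshold before the positivity-constraint boundary is
#' reported at the boundary and flagged `"boundary"`; a side that never
#' reaches it at all is reported open (`+/-Inf`) and flagged `"open"`.
#'
#' @inheritParams fit_mle
#' @param which `"alpha"` or `"beta"`.
#' @return length-2 numeric `(lo, hi)` with attribute `flags`.
#' @export
profile_ci <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                       which = c("alpha", "beta"), level = 0.95) {
  form <- match.arg(form)
  which <- match.arg(which)
  if (form == "linear" && which == "beta") {
    stop("the linear form has no beta coefficient")
  }
  fit <- fit_mle(cohort, doses, form, ci = TRUE, level = level)
  if (!fit$converged) stop("no converged MLE; cannot profile")
  ci <- if (which == "alpha") fit$ci_alpha else fit$ci_beta
  flags <- if (which == "alpha") fit$diagnostics$ci_alpha_flags
           else fit$diagnostics$ci_beta_flags
  structure(ci, flags = flags)
}

#' Akaike information criterion of a converged fit
#'
#' `-2 loglik + 2 p` with `p = 3` free parameters for the linear-quadratic
#' form (`alpha`, `beta`, `kappa`) and `p = 2` for the linear form.
#'
#' @param fit a converged `doserr_fit`.
#' @return scalar AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "doserr_fit"))
  if (!isTRUE(fit$converged)) stop("AIC requested for an unconverged fit")
  fit$aic
}

#' Serialize a fit to JSON
#'
#' @param fit a `doserr_fit`.
#' @return a JSON string (method, estimates, intervals, loglik, AIC,
#'   convergence flags).
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "doserr_fit"))
  jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}
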