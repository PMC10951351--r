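#' Settings for the quasi-2DMC Bayesian model averaging sampler
#'
#' Defaults follow the simulation study's Metropolis-Hastings setup:
#' normal priors with mean 0 and SD 1000 on all parameters, random-walk
#' proposal SDs of 0.2 for `kappa`, 1 for the dose-response coefficients
#' and 2 for the mixture-weight parameters `lambda` (proposed jointly in
#' blocks of 10), two chains, 1000 burn-in iterations and 1000 retained
#' iterations per chain, and a Brooks-Gelman-Rubin convergence threshold of
#' 1.03.
#'
#' @param prior_sd prior SD for all parameters.
#' @param proposal_sd_kappa,proposal_sd_coef,proposal_sd_lambda random-walk
#'   proposal SDs.
#' @param lambda_block block size for joint lambda proposals.
#' @param n_chains number of chains (>= 2, needed for the BGR statistic).
#' @param n_burnin,n_keep discarded and retained iterations per chain.
#' @param bgr_threshold convergence threshold on the BGR statistic.
#' @return an object of class `doserr_bma_settings`.
#' @export
bma_settings <- function(prior_sd = 1000, proposal_sd_kappa = 0.2,
                         proposal_sd_coef = 1, proposal_sd_lambda = 2,
                         lambda_block = 10, n_chains = 2,
                         n_burnin = 1000, n_keep = 1000,
                         bgr_threshold = 1.03) {
  stopifnot(prior_sd > 0, proposal_sd_kappa > 0, proposal_sd_coef > 0,
            proposal_sd_lambda > 0, lambda_block >= 1, n_chains >= 2,
            n_burnin >= 0, n_keep >= 10)
  structure(list(prior_sd = prior_sd,
                 proposal_sd_kappa = proposal_sd_kappa,
                 proposal_sd_coef = proposal_sd_coef,
                 proposal_sd_lambda = proposal_sd_lambda,
                 lambda_block = as.integer(lambda_block),
                 n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_keep = as.integer(n_keep),
                 bgr_threshold = bgr_threshold),
            class = "doserr_bma_settings")
}

#' Softmax mixture probabilities over dose vectors
#'
#' Maps the `m - 1` free parameters `lambda` to the probability vector of
#' length `m`: `p_j = exp(lambda_j) / (1 + sum(exp(lambda)))` for
#' `j < m` and `p_m = 1 / (1 + sum(exp(lambda)))`, stabilized with
#' log-sum-exp so the result sums to 1 for any real input.
#'
#' @param lambdas numeric vector of length `m - 1` (may be length 0).
#' @return probability vector of length `m`.
#' @export
#' @examples
#' softmax_probs(numeric(0))      # m = 1
#' softmax_probs(log(2))          # c(2/3, 1/3)
softmax_probs <- function(lambdas) {
  z <- c(lambdas, 0)
  p <- exp(z - logsumexp(z))
  p / sum(p)
}

#' Mixture log-likelihood over dose-vector realizations
#'
#' `log sum_k p_k L_k(alpha, beta, kappa)` with `L_k` the grouped Poisson
#' likelihood at dose vector `k`, stabilized with log-sum-exp. With uniform
#' weights this equals the Monte Carlo maximum likelihood objective.
#' Returns `-Inf` when the positivity constraint fails for every vector
#' with positive weight.
#'
#' @param alpha,beta,kappa model parameters.
#' @param p mixture weights summing to 1.
#' @param cohort a [grouped_cohort()].
#' @param doses a [dose_vector_set()].
#' @return scalar log-likelihood.
#' @export
mixture_log_likelihood <- function(alpha, beta, kappa, p, cohort, doses) {
  D <- doses$vectors
  if (length(p) != nrow(D)) stop("p must have one weight per dose vector")
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  ll <- vapply(seq_len(nrow(D)), function(k)
    rr_loglik(alpha, beta, kappa, cohort, D[k, ]), numeric(1))
  keep <- p > 0
  if (!any(keep)) return(-Inf)
  logsumexp(log(p[keep]) + ll[keep])
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' `sqrt((W (n - 1) / n + B / n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the chain means times
#' `n`. For identical chains the value is `sqrt((n - 1) / n)`, i.e. 1 up to
#' the `(n - 1)/n` factor. Zero within-chain variance is flagged with a
#' warning and yields `NaN`.
#'
#' @param chains a list of numeric vectors (one per chain, equal length
#'   `n >= 10`), or a matrix with one column per chain.
#' @return scalar BGR statistic.
#' @export
bgr_statistic <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2) stop("need >= 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 10) stop("chains must share a length >= 10")
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) {
    warning("zero within-chain variance; BGR undefined")
    return(NaN)
  }
  B <- n * var(vapply(chains, mean, numeric(1)))
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Quasi-2DMC with Bayesian model averaging
#'
#' Fits the grouped relative-risk model by Bayesian model averaging over
#' the `m` dose-vector realizations: the posterior is the mixture of
#' single-vector posteriors weighted by softmax probabilities
#' ([softmax_probs()]), sampled by alternating Metropolis-Hastings steps
#' that (a) update `kappa`, `alpha` (and `beta`) one at a time against the
#' mixture likelihood times the priors, and (b) update the `lambda`
#' parameters in consecutive blocks with a single joint accept per block.
#' Runs `n_chains` chains from overdispersed starts, discards the burn-in
#' and summarizes the pooled retained draws by posterior means and
#' equal-tail 95% credible intervals.
#'
#' Convergence diagnostics (per-parameter BGR statistic and acceptance
#' rates) are always reported; the fit is marked unconverged when any BGR
#' exceeds the threshold or a coefficient acceptance rate falls outside
#' 5-80%.
#'
#' @param cohort a [grouped_cohort()].
#' @param doses a [dose_vector_set()].
#' @param form `"linear-quadratic"` or `"linear"`.
#' @param settings a [bma_settings()].
#' @param seed integer seed (chains use derived sub-seeds).
#' @return list with `summary` (posterior means, intervals, BGR,
#'   acceptance rates, posterior mean mixture weights) and `fit` (a
#'   `doserr_fit` with method tag `"quasi_2dmc_bma"`).
#' @export
run_quasi_2dmc_bma <- function(cohort, doses,
                               form = c("linear-quadratic", "linear"),
                               settings = bma_settings(), seed = 1L) {
  form <- match.arg(form)
  linear <- form == "linear"
  D <- doses$vectors
  k0 <- log(cohort$n_total_cases / sum(cohort$person_years))
  chains <- lapply(seq_len(settings$n_chains), function(c) {
    # overdispersed starts: chain c offset by 2 proposal SDs per coefficient
    off <- 2 * (c - 1)
    with_seed(derive_seed(seed, "bma-chain", c),
              cpp_bma_chain(as.numeric(cohort$cases), cohort$person_years,
                            D, linear,
                            settings$prior_sd, settings$proposal_sd_kappa,
                            settings$proposal_sd_coef,
                            settings$proposal_sd_lambda,
                            settings$lambda_block,
                            settings$n_burnin, settings$n_keep,
                            k0 + off * settings$proposal_sd_kappa,
                            0 + off * settings$proposal_sd_coef,
                            if (linear) 0 else off * settings$proposal_sd_coef,
                            0))
  })
  draws <- lapply(chains, `[[`, "draws")   # n_keep x 3 (alpha, beta, kappa)
  pooled <- do.call(rbind, draws)
  par_idx <- if (linear) c(alpha = 1, kappa = 3) else
    c(alpha = 1, beta = 2, kappa = 3)
  bgr <- vapply(par_idx, function(j)
    bgr_statistic(lapply(draws, function(d) d[, j])), numeric(1))
  acc <- colMeans(do.call(rbind, lapply(chains, `[[`, "accept")))
  names(acc) <- c("kappa", "alpha", "beta", "lambda_block")
  if (linear) acc <- acc[names(acc) != "beta"]
  p_mean <- colMeans(do.call(rbind, lapply(chains, `[[`, "p_mean")))

  qi <- function(j) unname(quantile(pooled[, j], c(0.025, 0.975)))
  mean_a <- mean(pooled[, 1])
  mean_b <- if (linear) NA_real_ else mean(pooled[, 2])
  mean_k <- mean(pooled[, 3])
  theta_acc <- acc[names(acc) != "lambda_block"]
  converged <- all(is.finite(bgr)) && all(bgr <= settings$bgr_threshold) &&
    all(theta_acc >= 0.05 & theta_acc <= 0.80)
  diag <- list(bgr = bgr, acceptance = acc,
               bgr_threshold = settings$bgr_threshold)
  if (!converged) diag$reason <- "BGR above threshold or acceptance outside [5%, 80%]"
  summary <- list(mean_alpha = mean_a, mean_beta = mean_b,
                  mean_kappa = mean_k,
                  ci_alpha = qi(1),
                  ci_beta = if (linear) NULL else qi(2),
                  ci_kappa = qi(3),
                  bgr = bgr, acceptance = acc, p_weights_mean = p_mean)
  fit <- fit_result("quasi_2dmc_bma", form, mean_a, mean_b, mean_k,
                    NA_real_, ci_alpha = summary$ci_alpha,
                    ci_beta = summary$ci_beta, converged = converged,
                    diagnostics = diag)
  list(summary = summary, fit = fit)
}

#' Per-dose-vector fits for frequentist model averaging
#'
#' Fits the grouped model to each of the `m` dose vectors, recording the
#' maximum-likelihood estimates, profile 95% confidence intervals, AIC,
#' and the interval-derived standard deviations
#' `SD = min(est - lo, hi - est) / 1.96` (the minimum half-width divided by
#' the normal 97.5% centile). When one interval side is unbounded the
#' finite side's half-width is used and the vector is flagged; vectors with
#' no finite side, or unconverged fits, are excluded with a logged count.
#'
#' @inheritParams run_quasi_2dmc_bma
#' @param level confidence level for the per-vector profile intervals.
#' @return a data.frame with one row per dose vector (estimates, CIs, AIC,
#'   SDs, flags); attribute `n_excluded` counts excluded vectors.
#' @export
fma_fit_all <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                        level = 0.95) {
  form <- match.arg(form)
  linear <- form == "linear"
  q <- qchisq(level, df = 1)
  z <- qnorm(1 - (1 - level) / 2)
  res <- cpp_fit_batch(as.numeric(cohort$cases), cohort$person_years,
                       doses$vectors, linear, q, TRUE)
  res <- as.data.frame(res)
  sd_from_ci <- function(est, lo, hi) {
    hw_lo <- est - lo
    hw_hi <- hi - est
    hw <- pmin(hw_lo, hw_hi)
    one_open <- is.infinite(hw_lo) != is.infinite(hw_hi)
    hw[one_open] <- pmin(hw_lo, hw_hi)[one_open]  # finite side
    hw[is.infinite(hw_lo) & is.infinite(hw_hi)] <- NA_real_
    hw / z
  }
  res$sd_alpha <- sd_from_ci(res$alpha, res$alo, res$ahi)
  res$sd_beta <- if (linear) NA_real_ else
    sd_from_ci(res$beta, res$blo, res$bhi)
  res$aic <- -2 * res$loglik + 2 * npar_for(form)
  res$usable <- res$conv > 0.5 & is.finite(res$aic) &
    is.finite(res$sd_alpha) & (linear | is.finite(res$sd_beta))
  res$flag_open_ci <- is.infinite(res$alo) | is.infinite(res$ahi) |
    (!linear & (is.infinite(res$blo) | is.infinite(res$bhi)))
  attr(res, "n_excluded") <- sum(!res$usable)
  res
}

#' AIC softmax weights
#'
#' `w_j = exp(-AIC_j / 2) / sum_k exp(-AIC_k / 2)` (lower AIC, higher
#' weight), stabilized with log-sum-exp and invariant to a common shift of
#' the AICs.
#'
#' @param aics numeric vector of AIC values (at least one finite).
#' @return weights summing to 1.
#' @export
#' @examples
#' fma_weights(c(0, 2))   # c(0.7311, 0.2689) approximately
fma_weights <- function(aics) {
  if (!any(is.finite(aics))) stop("all AIC values are infinite")
  z <- -aics / 2
  w <- exp(z - logsumexp(z))
  w / sum(w)
}

#' Combine per-vector fits by AIC-weighted normal sampling
#'
#' For each dose vector draws `k` samples per coefficient from
#' `N(estimate, SD^2)`, attaches weight `w_j / k` to each sample, and
#' reports the weighted mean as the central estimate with the weighted
#' 2.5% and 97.5% centiles as the interval. Results are stable in `k` over
#' the range 100-1000.
#'
#' @param fits data.frame from [fma_fit_all()].
#' @param weights AIC weights from [fma_weights()] (same length).
#' @param k samples per fit (default 100).
#' @param seed integer seed.
#' @param form model form of the fits.
#' @param level interval level.
#' @return a `doserr_fit` with method tag `"fma"`.
#' @export
fma_combine <- function(fits, weights, k = 100, seed = 1L,
                        form = c("linear-quadratic", "linear"),
                        level = 0.95) {
  form <- match.arg(form)
  linear <- form == "linear"
  stopifnot(k >= 1, nrow(fits) == length(weights))
  use <- fits$usable
  if (!any(use)) stop("no usable per-vector fits")
  w <- weights[use] / sum(weights[use])
  est_a <- fits$alpha[use]; sd_a <- fits$sd_alpha[use]
  m <- sum(use)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- with_seed(derive_seed(seed, "fma"), {
    samp_w <- rep(w / k, each = k)
    a_s <- rnorm(m * k, mean = rep(est_a, each = k), sd = rep(sd_a, each = k))
    res <- list(alpha = sum(samp_w * a_s) / sum(samp_w),
                ci_alpha = weighted_quantile(a_s, samp_w, pr))
    if (!linear) {
      b_s <- rnorm(m * k, mean = rep(fits$beta[use], each = k),
                   sd = rep(fits$sd_beta[use], each = k))
      res$beta <- sum(samp_w * b_s) / sum(samp_w)
      res$ci_beta <- weighted_quantile(b_s, samp_w, pr)
    }
    res
  })
  kap <- sum(w * fits$kappa[use])
  fit_result("fma", form, out$alpha,
             if (linear) NA_real_ else out$beta, kap, NA_real_,
             ci_alpha = out$ci_alpha,
             ci_beta = if (linear) NULL else out$ci_beta,
             converged = TRUE,
             diagnostics = list(n_excluded = attr(fits, "n_excluded"),
                                k_per_fit = k))
}

#' Frequentist model averaging in one call
#'
#' Convenience wrapper: [fma_fit_all()] + [fma_weights()] +
#' [fma_combine()].
#'
#' @inheritParams run_quasi_2dmc_bma
#' @param k samples per fit.
#' @return a `doserr_fit` with method tag `"fma"`.
#' @export
fit_fma <- function(cohort, doses, form = c("linear-quadratic", "linear"),
                    k = 100, seed = 1L) {
  form <- match.arg(form)
  fits <- fma_fit_all(cohort, doses, form)
  w <- fma_weights(ifelse(fits$usable, fits$aic, Inf))
  fma_combine(fits, w, k = k, seed = seed, form = form)
}
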