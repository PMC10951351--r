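# shared fixtures: a trimmed cohort keeps the unit tests fast while
# preserving the 5-group structure of the full design

small_groups <- function(n = c(30, 20, 15, 10, 5)) {
  dose_group_spec(n_individuals = n, person_years = 10 * n)
}

# a fixed, hand-checkable grouped cohort on the default central doses
toy_cohort <- function() {
  grouped_cohort(cases = c(60, 30, 80, 50, 30),
                 person_years = c(7000, 1500, 1000, 400, 100))
}

default_doses <- function() c(0.03, 0.12, 0.50, 1.50, 2.00)

# independent R-side oracle for the profiled log-likelihood: maximize
# rr_loglik over the nuisance parameters by brute numerical optimization
profile_loglik_oracle <- function(cohort, d, form, which, val) {
  if (form == "linear") {
    kfun <- function(a) log(cohort$n_total_cases /
                              sum(cohort$person_years * (1 + a * d)))
    return(rr_loglik(val, 0, kfun(val), cohort, d))
  }
  if (which == "alpha") {
    bmin <- max(-(1 + val * d) / d^2) + 1e-9
    o <- optimize(function(b) rr_loglik(val, b,
      log(cohort$n_total_cases / sum(cohort$person_years *
                                       (1 + val * d + b * d^2))),
      cohort, d), c(bmin, bmin + 4000), maximum = TRUE, tol = 1e-11)
  } else {
    amin <- max(-(1 + val * d^2) / d) + 1e-9
    o <- optimize(function(a) rr_loglik(a, val,
      log(cohort$n_total_cases / sum(cohort$person_years *
                                       (1 + a * d + val * d^2))),
      cohort, d), c(amin, amin + 4000), maximum = TRUE, tol = 1e-11)
  }
  o$objective
}
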