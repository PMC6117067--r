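# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: numerical integration + bisection for the piecewise
# hazard sampler, a hand-written product-limit estimator for the KM
# module, and direct partial-likelihood maximization for the Cox module.

# Piecewise-multiplied Weibull hazard inverted numerically: integrate the
# hazard by adaptive quadrature and bisect H(t) = -log(u).
oracle_piecewise_time <- function(shape, scale, starts, mults, u) {
  haz <- function(t) {
    m <- mults[findInterval(t, starts)]
    m * (shape / scale) * (t / scale)^(shape - 1)
  }
  H <- function(t) {
    if (t == 0) return(0)
    knots <- c(0, starts[starts < t & starts > 0], t)
    sum(vapply(seq_len(length(knots) - 1L), function(i) {
      stats::integrate(haz, knots[i], knots[i + 1L],
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
    }, numeric(1)))
  }
  target <- -log(u)
  hi <- max(c(starts, scale))
  while (H(hi) < target) {
    hi <- hi * 2
    if (hi > 1e9) return(Inf)
  }
  stats::uniroot(function(t) H(t) - target, c(1e-12, hi),
                 tol = 1e-10)$root
}

# Brute-force product-limit estimator at the distinct event times.
oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  surv <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    n_i <- sum(times >= et[i])
    d_i <- sum(times == et[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = et, surv = surv)
}

# Counting-process Cox partial log-likelihood for a covariate matrix X
# (no ties assumed in the fixtures that use this).
oracle_partial_loglik <- function(beta, start, stop, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (j in which(event == 1)) {
    at_risk <- start < stop[j] & stop >= stop[j]
    ll <- ll + eta[j] - log(sum(exp(eta[at_risk])))
  }
  ll
}

oracle_cox_coef <- function(start, stop, event, X) {
  X <- as.matrix(X)
  fn <- function(b) -oracle_partial_loglik(b, start, stop, event, X)
  stats::optim(rep(0, ncol(X)), fn, method = "BFGS",
               control = list(reltol = 1e-14))$par
}

# Small synthetic cohorts reused across test files.
make_trial <- function(n_per_arm = 300, seed = 11, model = NULL, ...) {
  if (is.null(model)) model <- default_dynamic_model()
  generate_trial(trial_design(n_per_arm = n_per_arm, seed = seed, ...),
                 model)
}

# A dynamic model with unit hazard ratios everywhere.
unit_hr_model <- function(base = default_dynamic_model(),
                          response_prob = c(treatment = 0,
                                            comparator = 0)) {
  ones <- function(terms) stats::setNames(rep(1, length(terms)), terms)
  dynamic_model(
    baseline_tp = base$baseline_tp, baseline_td = base$baseline_td,
    baseline_os = base$baseline_os, response_time = base$response_time,
    loss_of_response_time = base$loss_of_response_time,
    response_prob = response_prob,
    hr_table = hr_table(
      progression = ones(c("response", "favorable", "intermediate",
                           "treat_early", "treat_late")),
      discontinuation = ones(c("response", "post_response", "favorable",
                               "intermediate", "treat")),
      death = ones(c("response", "post_response", "favorable",
                     "intermediate", "treat_early", "treat_late"))),
    inflection = base$inflection)
}
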