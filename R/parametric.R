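# Standard parametric survival analysis: single-distribution fits to
# right-censored samples, AIC/BIC selection, diagnostics and extrapolation.
#
# Parameter conventions (fixed package-wide, natural scale):
#   weibull           shape, scale          S(t) = exp(-(t/scale)^shape)
#   exponential       rate                  S(t) = exp(-rate t)
#   lognormal         meanlog, sdlog        of log-time
#   loglogistic       shape, scale          S(t) = 1 / (1 + (t/scale)^shape)
#   gompertz          shape (real), rate    h(t) = rate e^(shape t)
#   generalized_gamma mu, sigma, Q          stable log-time location-scale-shape

.FAMILIES <- c("weibull", "exponential", "lognormal", "loglogistic",
               "gompertz", "generalized_gamma")

.flexsurv_dist <- function(family) {
  switch(family, weibull = "weibull", exponential = "exp",
         lognormal = "lnorm", loglogistic = "llogis",
         gompertz = "gompertz", generalized_gamma = "gengamma")
}

#' Right-censored survival sample
#'
#' @param times Positive event/censoring times in months.
#' @param events Event indicators (1 = event, 0 = right-censored).
#' @return An object of class `survival_sample`.
#' @export
survival_sample <- function(times, events) {
  events <- as.integer(events)
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(!is.finite(times)) || any(times <= 0)) stop("all times must be finite and > 0")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  structure(list(times = as.numeric(times), events = events),
            class = "survival_sample")
}

#' Extract an endpoint's survival sample from patient records
#'
#' @param records Patient records.
#' @param endpoint `"progression"`, `"discontinuation"` or `"death"`.
#' @return A [survival_sample()].
#' @export
endpoint_sample <- function(records, endpoint = c("progression",
                                                  "discontinuation",
                                                  "death")) {
  endpoint <- match.arg(endpoint)
  cls <- .endpoint_cols(endpoint)
  survival_sample(records[[cls[["obs"]]]], records[[cls[["ev"]]]])
}

#' Fit a parametric survival distribution
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)} for one of
#' six families via [flexsurv::flexsurvreg()], with standard errors from
#' the observed information matrix.
#'
#' @param sample A [survival_sample()]; must contain at least one event.
#' @param family One of `"weibull"`, `"exponential"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"generalized_gamma"`.
#' @return An object of class `parametric_fit` with elements `family`,
#'   `params` (named, natural scale), `se`, `loglik`, `aic`, `bic`, `k`,
#'   `n`, `n_events`, `converged` and the underlying `flexsurvreg` object.
#'   Non-convergence is flagged (with a warning), never silent.
#' @examples
#' s <- survival_sample(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' fit_parametric(s, "exponential")$params  # rate = 4/10
#' @export
fit_parametric <- function(sample, family = .FAMILIES) {
  stopifnot(inherits(sample, "survival_sample"))
  family <- match.arg(family)
  if (sum(sample$events) == 0) stop("all observations censored: cannot fit")
  df <- data.frame(t = sample$times, e = sample$events)
  fs <- flexsurv::flexsurvreg(survival::Surv(t, e) ~ 1, data = df,
                              dist = .flexsurv_dist(family))
  converged <- isTRUE(fs$opt$convergence == 0)
  if (!converged) warning("optimizer did not converge for family ", family)
  params <- stats::setNames(fs$res[, "est"], rownames(fs$res))
  se <- stats::setNames(fs$res[, "se"], rownames(fs$res))
  k <- fs$npars
  n <- length(sample$times)
  loglik <- fs$loglik
  structure(list(family = family, params = params, se = se,
                 loglik = loglik, aic = 2 * k - 2 * loglik,
                 bic = k * log(n) - 2 * loglik, k = k, n = n,
                 n_events = sum(sample$events), converged = converged,
                 sample_id = c(n = n, events = sum(sample$events),
                               checksum = sum(sample$times)),
                 flexsurv = fs),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("Parametric fit: %s (n = %d, events = %d)%s\n", x$family,
              x$n, x$n_events, if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  ", paste(sprintf("%s = %.4g (se %.3g)", names(x$params), x$params,
                          x$se), collapse = ", "), "\n", sep = "")
  cat(sprintf("  loglik %.3f, AIC %.2f, BIC %.2f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Distribution evaluators for a parametric fit
#'
#' `surv_function()`, `density_function()`, `hazard_function()`,
#' `cumhaz_function()` and `quantile_function()` return vectorized
#' functions of time (or probability) for the fitted distribution.
#'
#' @param fit A `parametric_fit`.
#' @return A function of one numeric vector argument.
#' @export
surv_function <- function(fit) {
  p <- fit$params
  switch(fit$family,
    weibull = function(t) stats::pweibull(t, p[["shape"]], p[["scale"]],
                                          lower.tail = FALSE),
    exponential = function(t) stats::pexp(t, p[["rate"]], lower.tail = FALSE),
    lognormal = function(t) stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                                          lower.tail = FALSE),
    loglogistic = function(t) flexsurv::pllogis(t, shape = p[["shape"]],
                                                scale = p[["scale"]],
                                                lower.tail = FALSE),
    gompertz = function(t) flexsurv::pgompertz(t, shape = p[["shape"]],
                                               rate = p[["rate"]],
                                               lower.tail = FALSE),
    generalized_gamma = function(t) flexsurv::pgengamma(t, mu = p[["mu"]],
                                                        sigma = p[["sigma"]],
                                                        Q = p[["Q"]],
                                                        lower.tail = FALSE))
}

#' @rdname surv_function
#' @export
density_function <- function(fit) {
  p <- fit$params
  switch(fit$family,
    weibull = function(t) stats::dweibull(t, p[["shape"]], p[["scale"]]),
    exponential = function(t) stats::dexp(t, p[["rate"]]),
    lognormal = function(t) stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = function(t) flexsurv::dllogis(t, shape = p[["shape"]],
                                                scale = p[["scale"]]),
    gompertz = function(t) flexsurv::dgompertz(t, shape = p[["shape"]],
                                               rate = p[["rate"]]),
    generalized_gamma = function(t) flexsurv::dgengamma(t, mu = p[["mu"]],
                                                        sigma = p[["sigma"]],
                                                        Q = p[["Q"]]))
}

#' @rdname surv_function
#' @export
hazard_function <- function(fit) {
  d <- density_function(fit); s <- surv_function(fit)
  function(t) d(t) / s(t)
}

#' @rdname surv_function
#' @export
cumhaz_function <- function(fit) {
  s <- surv_function(fit)
  function(t) -log(s(t))
}

#' @rdname surv_function
#' @export
quantile_function <- function(fit) {
  p <- fit$params
  switch(fit$family,
    weibull = function(q) stats::qweibull(q, p[["shape"]], p[["scale"]]),
    exponential = function(q) stats::qexp(q, p[["rate"]]),
    lognormal = function(q) stats::qlnorm(q, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = function(q) flexsurv::qllogis(q, shape = p[["shape"]],
                                                scale = p[["scale"]]),
    gompertz = function(q) flexsurv::qgompertz(q, shape = p[["shape"]],
                                               rate = p[["rate"]]),
    generalized_gamma = function(q) flexsurv::qgengamma(q, mu = p[["mu"]],
                                                        sigma = p[["sigma"]],
                                                        Q = p[["Q"]]))
}

#' Rank parametric fits by information criteria
#'
#' Sorts fits of the same sample by AIC with BIC as tie-break. Selection
#' is advisory: the ranked table is returned for inspection together with
#' the fits, and no family is discarded — the family carried into
#' extrapolation remains a user/config choice (Weibull by default in the
#' pipeline).
#'
#' @param fits A list of `parametric_fit` objects on the same sample.
#' @return A data frame (family, k, loglik, aic, bic, rank) ordered best
#'   first, with the fits attached as attribute `"fits"` in ranked order.
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "parametric_fit")))
  ids <- t(vapply(fits, function(f) f$sample_id, numeric(3)))
  if (any(apply(ids, 2, function(x) max(x) - min(x)) > 1e-8))
    stop("fits were made on different samples")
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)))
  ord <- order(tab$aic, tab$bic)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Diagnostic data series for a parametric fit
#'
#' Returns plot-ready series for graphical goodness-of-fit assessment:
#' the Kaplan-Meier log-cumulative-hazard points
#' \eqn{(\log t, \log(-\log \hat S(t)))}, the model-implied curve on the
#' same axes (for a Weibull this is a line with slope equal to the shape),
#' and a quantile-quantile series (observed KM-implied quantiles against
#' model quantiles).
#'
#' @param sample A [survival_sample()].
#' @param fit A `parametric_fit`.
#' @param grid_length Number of points for the model curve.
#' @return A list of data frames `km_cloglog`, `model_cloglog`, `qq`.
#' @export
diagnostics_series <- function(sample, fit, grid_length = 101L) {
  stopifnot(inherits(sample, "survival_sample"),
            inherits(fit, "parametric_fit"))
  km <- km_estimate(sample)
  pts <- km[km$n_event > 0 & km$surv > 0 & km$surv < 1 & km$time > 0, ]
  km_cloglog <- data.frame(log_time = log(pts$time),
                           cloglog = log(-log(pts$surv)))
  tgrid <- exp(seq(log(min(sample$times)), log(max(sample$times)),
                   length.out = grid_length))
  S <- surv_function(fit)(tgrid)
  ok <- S > 0 & S < 1
  model_cloglog <- data.frame(log_time = log(tgrid[ok]),
                              cloglog = log(-log(S[ok])))
  qf <- quantile_function(fit)
  qq <- data.frame(observed = pts$time, model = qf(1 - pts$surv))
  list(km_cloglog = km_cloglog, model_cloglog = model_cloglog, qq = qq)
}

#' Extrapolate a parametric fit over a long horizon
#'
#' Computes the fitted median (reported as not reached when the survival
#' function stays above 0.5 through the horizon, e.g. for an improper
#' Gompertz fit), the restricted mean survival time
#' \eqn{\int_0^{horizon} S(t)\,dt} by adaptive quadrature (absolute
#' tolerance 1e-6 months), and landmark survival probabilities.
#'
#' @param fit A `parametric_fit`.
#' @param horizon Months (> 0); default 300 (25 years).
#' @param landmarks Landmark months (default 36 and 60).
#' @return A list of class `extrapolation`: `median`, `median_reached`,
#'   `rmst`, `landmarks` (named vector), `horizon`.
#' @export
extrapolate <- function(fit, horizon = 300, landmarks = c(36, 60)) {
  stopifnot(inherits(fit, "parametric_fit"), horizon > 0,
            all(landmarks <= horizon))
  S <- surv_function(fit)
  reached <- S(horizon) <= 0.5
  med <- if (reached) quantile_function(fit)(0.5) else NA_real_
  rmst <- stats::integrate(S, 0, horizon, abs.tol = 1e-6,
                           subdivisions = 1000L)$value
  structure(list(median = med, median_reached = reached, rmst = rmst,
                 landmarks = stats::setNames(S(landmarks),
                                             paste0("s", landmarks)),
                 horizon = horizon), class = "extrapolation")
}

#' @export
print.extrapolation <- function(x, ...) {
  cat(sprintf("Median: %s months; RMST(%g mo): %.2f months\n",
              if (x$median_reached) sprintf("%.2f", x$median) else
                "not reached", x$horizon, x$rmst))
  cat("  landmarks:", paste(sprintf("%s = %.3f", names(x$landmarks),
                                    x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Fit all six parametric families to one endpoint
#'
#' Convenience wrapper producing the standard-parametric-analysis fit
#' table for one endpoint of one arm.
#'
#' @param sample A [survival_sample()].
#' @param families Families to fit (default all six).
#' @return A list of `parametric_fit` objects named by family.
#' @export
fit_all_families <- function(sample, families = .FAMILIES) {
  fits <- lapply(families, function(f) {
    tryCatch(fit_parametric(sample, f), error = function(e) NULL)
  })
  names(fits) <- families
  Filter(Negate(is.null), fits)
}
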