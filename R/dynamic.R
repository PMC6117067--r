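# Estimation of the dynamic model from patient-level data: reference-arm
# Weibull baselines, response-time submodels, piecewise-HR inflection
# assessment, and assembly of the full dynamic_model consumed by the
# microsimulation engine.

#' Fit the reference-arm Weibull baseline for one endpoint
#'
#' The microsimulation multiplies the baseline hazard by response-state
#' hazard ratios, so the baseline must represent the nonresponse state:
#' the fit is restricted to comparator-arm, poor-risk patients who never
#' achieved an objective response during follow-up (their whole observed
#' exposure is response-free). The small selection effect this induces is
#' acknowledged in the package vignette.
#'
#' @param records Patient records.
#' @param endpoint `"progression"`, `"discontinuation"` or `"death"`.
#' @param min_events Minimum number of events required in the reference
#'   subset (default 5); fewer raises an error suggesting a pooled fit.
#' @return A list with `params` ([weibull_params()]), the underlying
#'   `parametric_fit`, and `n`, `n_events` of the reference subset.
#' @export
fit_reference_baselines <- function(records, endpoint = c("progression",
                                                          "discontinuation",
                                                          "death"),
                                    min_events = 5L) {
  endpoint <- match.arg(endpoint)
  never_resp <- !records$responded |
    (!is.na(records$t_response) & records$t_response > records$c_admin)
  idx <- records$arm == "comparator" & records$mskcc == "poor" & never_resp
  if (!any(idx)) stop("reference subset (comparator, poor risk) is empty")
  sub <- records[idx, , drop = FALSE]
  cls <- .endpoint_cols(endpoint)
  ev <- sub[[cls[["ev"]]]]
  if (endpoint == "progression" && !is.null(sub$tp_via_loss))
    ev <- ifelse(sub$tp_via_loss, 0L, ev)
  if (sum(ev) < min_events)
    stop("only ", sum(ev), " events in the reference subset (need >= ",
         min_events, "); pool strata or arms before fitting")
  fit <- fit_parametric(survival_sample(sub[[cls[["obs"]]]], ev), "weibull")
  list(params = weibull_params(fit$params[["shape"]], fit$params[["scale"]]),
       fit = fit, n = nrow(sub), n_events = sum(ev))
}

#' Fit the response-time submodels
#'
#' Log-normal maximum likelihood on observed response times (responders
#' only: the responder fraction is a separate Bernoulli parameter
#' estimated as the observed response rate per arm), and Gompertz maximum
#' likelihood on time from response to loss of response, right-censored
#' at the end of follow-up (`min(c_admin, death)`). A negative Gompertz
#' shape is permitted and encodes a durable-responder fraction that never
#' loses response. With responders but no observed losses the Gompertz
#' fit is degenerate: an improper near-flat fit is returned with a
#' warning.
#'
#' @param records Patient records.
#' @param min_responses Minimum observed responses required (default 5).
#' @return A list with `response_time` ([lognormal_params()]),
#'   `loss_of_response_time` ([gompertz_params()]), `response_prob`
#'   (named per-arm observed response rates), counts, and `loss_fit`
#'   (the `flexsurvreg` object, or `NULL` when degenerate).
#' @export
fit_response_models <- function(records, min_responses = 5L) {
  obs_resp <- records$responded & !is.na(records$t_response) &
    records$t_response <= records$c_admin
  if (sum(obs_resp) < min_responses)
    stop("only ", sum(obs_resp), " observed responses (need >= ",
         min_responses, ")")
  rt <- records$t_response[obs_resp]
  mu <- mean(log(rt))
  sigma <- sqrt(mean((log(rt) - mu)^2))  # ML (1/n) variant
  # end of follow-up for response status: administrative cutoff or death
  fup_end <- pmin(records$c_admin, records$t_death %||% records$obs_os)[obs_resp]
  t_loss <- records$t_loss_response[obs_resp]
  lost <- is.finite(t_loss) & t_loss <= fup_end
  dur <- ifelse(lost, t_loss, fup_end) - rt
  loss_fit <- NULL
  if (sum(lost) == 0) {
    warning("no losses of response observed: returning a degenerate ",
            "improper Gompertz fit")
    loss <- gompertz_params(shape = -1, rate = 1e-8)
  } else {
    fs <- flexsurv::flexsurvreg(survival::Surv(dur, lost) ~ 1,
                                data = data.frame(dur = dur, lost = lost),
                                dist = "gompertz")
    loss <- gompertz_params(fs$res["shape", "est"], fs$res["rate", "est"])
    loss_fit <- fs
  }
  rate <- vapply(.ARM_LEVELS, function(a)
    mean(obs_resp[records$arm == a]), numeric(1))
  list(response_time = lognormal_params(mu, sigma),
       loss_of_response_time = loss,
       response_prob = rate,
       n_responses = sum(obs_resp), n_losses = sum(lost),
       loss_fit = loss_fit)
}

#' Assess proportional hazards and choose the treatment-effect inflection
#'
#' For each candidate inflection time, rebuilds the counting process with
#' that split, fits the multivariate Cox model with a treatment-by-period
#' interaction, and records the partial log-likelihood and the Wald test
#' of equal early/late treatment effects. The candidate maximizing the
#' log-likelihood is returned as `chosen`, together with a
#' Schoenfeld-residual global proportional-hazards test on the
#' no-interaction model. The final inflection remains a configuration
#' choice; `chosen` is advisory.
#'
#' @param records Patient records.
#' @param endpoint Endpoint to assess (default `"death"`).
#' @param candidates Candidate inflection months (default `c(2, 3, 4, 6)`).
#'   Candidates at or beyond the last event time are skipped with a
#'   warning.
#' @param covariates Covariates for the model (default the multivariate
#'   set).
#' @return A list of class `ph_assessment`: `chosen`, `table` (candidate,
#'   loglik, wald_z, wald_p), `ph_global_p`.
#' @export
assess_ph <- function(records, endpoint = "death",
                      candidates = c(2, 3, 4, 6),
                      covariates = c("response_state", "mskcc",
                                     "treatment")) {
  stopifnot(length(candidates) >= 2L)
  cls <- .endpoint_cols(endpoint)
  last_event <- max(records[[cls[["obs"]]]][records[[cls[["ev"]]]] == 1])
  ok <- candidates < last_event
  if (any(!ok)) {
    warning("skipping candidate inflection(s) beyond the last event time: ",
            paste(candidates[!ok], collapse = ", "))
    candidates <- candidates[ok]
  }
  rows_list <- lapply(candidates, function(cand)
    build_counting_process(records, endpoint, inflection = cand))
  res <- lapply(seq_along(candidates), function(i) {
    fit <- fit_cox(rows_list[[i]], covariates, treatment_effect = "piecewise")
    b <- fit$table
    ie <- match("treat_early", b$term); il <- match("treat_late", b$term)
    V <- fit$fit$var
    ke <- match("treat_early", names(stats::coef(fit$fit)))
    kl <- match("treat_late", names(stats::coef(fit$fit)))
    z <- (b$coef[ie] - b$coef[il]) /
      sqrt(V[ke, ke] + V[kl, kl] - 2 * V[ke, kl])
    data.frame(candidate = candidates[i], loglik = fit$loglik,
               wald_z = z, wald_p = 2 * stats::pnorm(-abs(z)))
  })
  tab <- do.call(rbind, res)
  base_fit <- fit_cox(rows_list[[1]], covariates,
                      treatment_effect = "constant")
  zph <- survival::cox.zph(base_fit$fit, transform = "km")
  structure(list(chosen = tab$candidate[which.max(tab$loglik)],
                 table = tab,
                 ph_global_p = zph$table["GLOBAL", "p"]),
            class = "ph_assessment")
}

#' @export
print.ph_assessment <- function(x, ...) {
  cat(sprintf("Piecewise-HR inflection assessment (global PH test p = %.3g)\n",
              x$ph_global_p))
  print(x$table, row.names = FALSE)
  cat("Chosen inflection:", x$chosen, "months (advisory)\n")
  invisible(x)
}

#' Estimate the full dynamic model from patient-level data
#'
#' Assembles a [dynamic_model()] by combining (i) reference-arm Weibull
#' baselines per endpoint ([fit_reference_baselines()]), (ii) the
#' log-normal/Gompertz response submodels and per-arm observed response
#' rates ([fit_response_models()]), and (iii) the multivariate
#' hazard-ratio table ([fit_hr_table()]). The Cox hazard ratios are
#' applied multiplicatively to the refitted Weibull baseline (rather than
#' to the semiparametric Cox baseline); the resulting model is the input
#' of [simulate_dynamic()].
#'
#' @param records Patient records.
#' @param inflection Treatment-period inflection in months (default 3,
#'   assessable with [assess_ph()]).
#' @return A list with `model` (the [dynamic_model()]), `hr_fit`
#'   (estimates and Cox fits), `baselines`, `response_models`.
#' @export
fit_dynamic_model <- function(records, inflection = 3) {
  hrf <- fit_hr_table(records, inflection = inflection)
  bl <- lapply(.ENDPOINTS, function(ep) fit_reference_baselines(records, ep))
  names(bl) <- .ENDPOINTS
  rm_ <- fit_response_models(records)
  model <- dynamic_model(
    baseline_tp = bl$progression$params,
    baseline_td = bl$discontinuation$params,
    baseline_os = bl$death$params,
    response_time = rm_$response_time,
    loss_of_response_time = rm_$loss_of_response_time,
    response_prob = rm_$response_prob,
    hr_table = hrf$hr_table,
    inflection = inflection)
  list(model = model, hr_fit = hrf, baselines = bl, response_models = rm_)
}
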