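# Episode-splitting of patient records into counting-process form
# (start, stop] for time-dependent Cox regression. Episode boundaries are
# the treatment-effect inflection point, response achievement, and (for
# discontinuation and death) loss of response; covariates are constant
# within an episode and evaluated at its start.

.endpoint_cols <- function(endpoint) {
  switch(endpoint,
         progression = c(obs = "obs_tp", ev = "ev_tp"),
         discontinuation = c(obs = "obs_td", ev = "ev_td"),
         death = c(obs = "obs_os", ev = "ev_os"))
}

#' Build counting-process data for one endpoint
#'
#' Splits each subject's observed follow-up for the chosen endpoint into
#' at-risk episodes at (i) the treatment-effect inflection point, (ii) the
#' observed response time and (iii) the observed loss-of-response time
#' (discontinuation and death only). Each subject's episodes are disjoint,
#' contiguous from 0 to the observed time, and carry the response state,
#' MSKCC group, arm and treatment period in force at the episode start.
#'
#' For the progression endpoint there is no post-response state: a
#' responder's progression follow-up ends at loss of response. A
#' progression event that is realized *by* loss of response
#' (`tp_via_loss`) terminates the at-risk period without counting as a
#' hazard-driven progression event, because the progression hazard model
#' governs spontaneous progression only; the deterministic
#' progression-at-loss component belongs to the loss-of-response submodel.
#'
#' @param records Patient records ([generate_trial()] / [read_trial_csv()]).
#' @param endpoint `"progression"`, `"discontinuation"` or `"death"`.
#' @param inflection Treatment-period split time in months (default 3).
#' @return A `counting_process` data frame with columns `id`, `start`,
#'   `stop`, `event`, `response_state`, `mskcc`, `arm`, `period`
#'   (`"early"` = at or before the inflection, `"late"` = after).
#' @examples
#' trial <- generate_trial(trial_design(n_per_arm = 30, seed = 2),
#'                         default_dynamic_model())
#' cp <- build_counting_process(trial, "death")
#' head(cp)
#' @export
build_counting_process <- function(records, endpoint = c("progression",
                                                         "discontinuation",
                                                         "death"),
                                   inflection = 3) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.numeric(inflection), inflection > 0)
  cls <- .endpoint_cols(endpoint)
  obs <- records[[cls[["obs"]]]]
  ev <- records[[cls[["ev"]]]]
  if (is.null(obs) || is.null(ev)) stop("records lack observed columns; run apply_censoring()")
  if (any(obs <= 0)) stop("non-positive observed time")
  t_resp <- records$t_response
  t_loss <- records$t_loss_response
  if (any(!is.na(t_resp) & t_resp >= records$obs_os & records$ev_os == 1))
    stop("response time at or after observed death: generator contract violated")
  hazard_event <- ev
  if (endpoint == "progression" && !is.null(records$tp_via_loss))
    hazard_event <- ifelse(records$tp_via_loss, 0L, ev)
  n <- nrow(records)
  r <- ifelse(is.na(t_resp), Inf, t_resp)
  l <- if (endpoint == "progression") rep(Inf, n)
       else ifelse(is.na(t_loss), Inf, t_loss)
  # sorted candidate boundaries per subject (r < l always)
  a <- pmin(inflection, r)
  cmax <- pmax(inflection, l)
  b <- pmin(pmax(inflection, r), l)
  # clamp boundaries at the observed time; zero-length episodes drop out
  a <- pmin(a, obs); b <- pmin(b, obs); cmax <- pmin(cmax, obs)
  starts <- c(rbind(0, a, b, cmax))
  stops <- c(rbind(a, b, cmax, obs))
  idx <- rep(seq_len(n), each = 4L)
  keep <- stops > starts
  starts <- starts[keep]; stops <- stops[keep]; idx <- idx[keep]
  is_last <- stops == obs[idx]
  state <- ifelse(starts >= r[idx] & starts < l[idx], "response",
                  ifelse(starts >= l[idx], "post_response", "nonresponse"))
  out <- data.frame(
    id = records$id[idx],
    start = starts, stop = stops,
    event = ifelse(is_last, hazard_event[idx], 0L),
    response_state = factor(state, levels = .STATE_LEVELS),
    mskcc = factor(as.character(records$mskcc[idx]), levels = .MSKCC_LEVELS),
    arm = factor(as.character(records$arm[idx]), levels = .ARM_LEVELS),
    period = factor(ifelse(starts < inflection, "early", "late"),
                    levels = c("early", "late")))
  attr(out, "endpoint") <- endpoint
  attr(out, "inflection") <- inflection
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Fit a Cox model on counting-process data
#'
#' Maximizes the counting-process partial likelihood (Efron ties by
#' default) via [survival::coxph()] and reports hazard ratios with Wald
#' standard errors, 95% confidence intervals and p-values. Supports
#' univariate runs (a single covariate) and the multivariate specification
#' (treatment + response state + MSKCC risk). The treatment effect can be
#' piecewise over the inflection periods (`treat_early`, `treat_late`) or
#' a single period-constant term (`treat`), the latter being the
#' discontinuation-endpoint convention.
#'
#' @param rows A `counting_process` data frame from
#'   [build_counting_process()].
#' @param covariates Character subset of
#'   `c("response_state", "mskcc", "treatment")`.
#' @param treatment_effect `"piecewise"` or `"constant"`.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return An object of class `cox_hr_fit`: a list with `table` (term,
#'   coef, hr, se, lower, upper, p, monotone flag), `loglik`, `n`,
#'   `n_events`, `endpoint` and the underlying `coxph` fit. Covariates
#'   without variation raise a collinearity error; monotone-likelihood
#'   terms (no events in a level) are flagged with infinite confidence
#'   intervals rather than failing.
#' @export
fit_cox <- function(rows, covariates = c("response_state", "mskcc",
                                         "treatment"),
                    treatment_effect = c("piecewise", "constant"),
                    ties = "efron") {
  stopifnot(is.data.frame(rows))
  treatment_effect <- match.arg(treatment_effect)
  covariates <- match.arg(covariates, several.ok = TRUE)
  df <- as.data.frame(rows)
  if (sum(df$event) < 1) stop("need at least one event")
  terms <- character(0)
  if ("response_state" %in% covariates) {
    df$response_state <- droplevels(factor(df$response_state,
                                           levels = .STATE_LEVELS))
    if (nlevels(df$response_state) < 2L)
      stop("response_state has no variation: degenerate/collinear covariate")
    terms <- c(terms, "response_state")
  }
  if ("mskcc" %in% covariates) {
    df$mskcc <- droplevels(factor(df$mskcc, levels = .MSKCC_LEVELS))
    if (nlevels(df$mskcc) < 2L)
      stop("mskcc has no variation: degenerate/collinear covariate")
    terms <- c(terms, "mskcc")
  }
  if ("treatment" %in% covariates) {
    trt <- df$arm == "treatment"
    if (!any(trt) || all(trt))
      stop("treatment arm has no variation: degenerate/collinear covariate")
    if (treatment_effect == "constant") {
      df$treat <- as.integer(trt)
      terms <- c(terms, "treat")
    } else {
      df$treat_early <- as.integer(trt & df$period == "early")
      df$treat_late <- as.integer(trt & df$period == "late")
      terms <- c(terms, "treat_early", "treat_late")
    }
  }
  if (!length(terms)) stop("no covariates requested")
  f <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = df, ties = ties)
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("collinear covariates: ", paste(names(beta)[is.na(beta)],
                                         collapse = ", "))
  se <- sqrt(diag(fit$var))
  term_names <- sub("^response_state", "", sub("^mskcc", "", names(beta)))
  monotone <- se > 50 | abs(beta) > 15
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    term = term_names, coef = unname(beta), hr = exp(unname(beta)),
    se = unname(se),
    lower = ifelse(monotone, 0, exp(beta - z * se)),
    upper = ifelse(monotone, Inf, exp(beta + z * se)),
    p = 2 * stats::pnorm(-abs(beta / se)),
    monotone = unname(monotone), row.names = NULL)
  structure(list(table = tab, loglik = unname(fit$loglik[2]),
                 loglik_null = unname(fit$loglik[1]),
                 n = length(unique(df$id)), n_events = sum(df$event),
                 endpoint = attr(rows, "endpoint"), fit = fit),
            class = "cox_hr_fit")
}

#' @export
print.cox_hr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox fit%s: %d subjects, %d events, partial loglik %.2f\n",
              if (!is.null(x$endpoint)) paste0(" [", x$endpoint, "]") else "",
              x$n, x$n_events, x$loglik))
  tab <- x$table
  tab$hr <- signif(tab$hr, digits); tab$lower <- signif(tab$lower, digits)
  tab$upper <- signif(tab$upper, digits); tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "hr", "lower", "upper", "p")], row.names = FALSE)
  invisible(x)
}

#' Fit the full multivariate hazard-ratio table
#'
#' Runs [build_counting_process()] + [fit_cox()] for the three endpoints
#' with their endpoint-specific treatment parameterization (piecewise for
#' progression and death, period-constant for discontinuation) and stacks
#' the estimates into one table mirroring the dynamic-model hazard-ratio
#' layout.
#'
#' @param records Patient records.
#' @param inflection Treatment-period inflection in months (default 3).
#' @return A list with `estimates` (data frame: endpoint, term, hr, se,
#'   lower, upper, p), `fits` (the three `cox_hr_fit` objects) and
#'   `hr_table` (an [hr_table()] built from the point estimates).
#' @export
fit_hr_table <- function(records, inflection = 3) {
  fits <- lapply(.ENDPOINTS, function(ep) {
    cp <- build_counting_process(records, ep, inflection = inflection)
    fit_cox(cp, treatment_effect = if (ep == "discontinuation") "constant"
                                   else "piecewise")
  })
  names(fits) <- .ENDPOINTS
  est <- do.call(rbind, lapply(.ENDPOINTS, function(ep) {
    cbind(endpoint = ep, fits[[ep]]$table)
  }))
  hrs <- lapply(.ENDPOINTS, function(ep) {
    v <- fits[[ep]]$table
    stats::setNames(v$hr, v$term)[.hr_terms(ep)]
  })
  names(hrs) <- .ENDPOINTS
  list(estimates = est, fits = fits,
       hr_table = hr_table(progression = hrs$progression,
                           discontinuation = hrs$discontinuation,
                           death = hrs$death))
}
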