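# Hazard-ratio table, dynamic model specification and trial design objects.
#
# Endpoints are "progression" (TTP), "discontinuation" (TTD) and "death"
# (TTDeath). Covariate reference levels are fixed package-wide: comparator
# arm, nonresponse state, poor MSKCC risk. The treatment effect on
# progression and death is piecewise (<= inflection / > inflection, default
# 3 months: terms `treat_early` / `treat_late`); discontinuation uses a
# single period-constant treatment term `treat`.

.ENDPOINTS <- c("progression", "discontinuation", "death")
.MSKCC_LEVELS <- c("poor", "favorable", "intermediate")
.ARM_LEVELS <- c("comparator", "treatment")
.STATE_LEVELS <- c("nonresponse", "response", "post_response")

.hr_terms <- function(endpoint) {
  switch(endpoint,
    progression = c("response", "favorable", "intermediate",
                    "treat_early", "treat_late"),
    discontinuation = c("response", "post_response", "favorable",
                        "intermediate", "treat"),
    death = c("response", "post_response", "favorable", "intermediate",
              "treat_early", "treat_late"))
}

#' Hazard-ratio table for the dynamic model
#'
#' Multiplicative hazard ratios per endpoint, all relative to the reference
#' state (comparator arm, nonresponse, poor MSKCC risk). Progression has no
#' post-response term: once a responder loses response the progression
#' endpoint is realized (loss of response manifests as progression), so a
#' post-response progression hazard is structurally absent.
#'
#' @param progression,discontinuation,death Named numeric vectors of
#'   positive hazard ratios. Required names: `response`, `favorable`,
#'   `intermediate` for all three; `post_response` for discontinuation and
#'   death; `treat_early`, `treat_late` for progression and death
#'   (piecewise treatment effect); `treat` for discontinuation (single
#'   period-constant treatment effect).
#' @return An object of class `hr_table`.
#' @examples
#' default_hr_table()
#' @export
hr_table <- function(progression, discontinuation, death) {
  tabs <- list(progression = progression,
               discontinuation = discontinuation,
               death = death)
  for (ep in .ENDPOINTS) {
    v <- tabs[[ep]]
    need <- .hr_terms(ep)
    if (!is.numeric(v) || is.null(names(v)))
      stop("hazard ratios for ", ep, " must be a named numeric vector")
    missing_terms <- setdiff(need, names(v))
    if (length(missing_terms))
      stop("missing ", ep, " terms: ", paste(missing_terms, collapse = ", "))
    extra <- setdiff(names(v), need)
    if (length(extra))
      stop("unsupported ", ep, " terms: ", paste(extra, collapse = ", "))
    if (any(!is.finite(v)) || any(v <= 0))
      stop("all hazard ratios must be finite and > 0")
    tabs[[ep]] <- v[need]
  }
  structure(tabs, class = "hr_table")
}

#' @export
print.hr_table <- function(x, ...) {
  cat("Hazard-ratio table (reference: comparator / nonresponse / poor risk)\n")
  for (ep in .ENDPOINTS) {
    cat(sprintf("  %-16s %s\n", ep,
                paste(sprintf("%s=%.3g", names(x[[ep]]), x[[ep]]),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Look up one hazard ratio
#'
#' @param tab An [hr_table()].
#' @param endpoint One of `"progression"`, `"discontinuation"`, `"death"`.
#' @param term Term name (see [hr_table()]).
#' @return A single hazard ratio.
#' @export
hr_get <- function(tab, endpoint, term) {
  stopifnot(inherits(tab, "hr_table"))
  endpoint <- match.arg(endpoint, .ENDPOINTS)
  v <- tab[[endpoint]][term]
  if (any(is.na(v))) stop("no term `", term, "` for endpoint ", endpoint)
  unname(v)
}

# Normalize response probabilities to a 2 x 3 matrix (arm x MSKCC level).
.resp_prob_matrix <- function(response_prob) {
  if (is.matrix(response_prob)) {
    if (!all(rownames(response_prob) %in% .ARM_LEVELS) ||
        !all(.ARM_LEVELS %in% rownames(response_prob)) ||
        !all(.MSKCC_LEVELS %in% colnames(response_prob)))
      stop("response_prob matrix needs rows {treatment, comparator} and ",
           "columns {poor, favorable, intermediate}")
    m <- response_prob[.ARM_LEVELS, .MSKCC_LEVELS]
  } else {
    if (is.null(names(response_prob)) ||
        !all(.ARM_LEVELS %in% names(response_prob)))
      stop("response_prob must be named with `treatment` and `comparator`")
    m <- cbind(poor = response_prob[.ARM_LEVELS],
               favorable = response_prob[.ARM_LEVELS],
               intermediate = response_prob[.ARM_LEVELS])
    rownames(m) <- .ARM_LEVELS
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("response probabilities must lie in [0, 1]")
  m
}

#' Dynamic model specification
#'
#' The full dynamic specification used both as the data-generating truth of
#' the synthetic trial and as the estimated model driving the DICE
#' microsimulation: reference-arm Weibull baselines for the three
#' endpoints, a log-normal time-to-response submodel, a Gompertz
#' time-to-loss-of-response submodel (negative shape allowed, encoding a
#' durable-responder fraction), per-arm (optionally per-arm-by-risk)
#' response probabilities, and the multiplicative [hr_table()].
#'
#' @param baseline_tp,baseline_td,baseline_os [weibull_params()] baselines
#'   for progression, discontinuation and death in the reference state
#'   (comparator arm, nonresponse, poor MSKCC risk).
#' @param response_time [lognormal_params()] for time from randomization to
#'   objective response among responders.
#' @param loss_of_response_time [gompertz_params()] for time from response
#'   to loss of response (improper allowed).
#' @param response_prob Either a named vector `c(treatment=, comparator=)`
#'   or a 2 x 3 matrix (rows `treatment`/`comparator`, columns
#'   `poor`/`favorable`/`intermediate`) of latent responder probabilities.
#' @param hr_table An [hr_table()].
#' @param inflection Treatment-effect inflection point in months (default 3).
#' @return An object of class `dynamic_model`.
#' @seealso [default_dynamic_model()], [fit_dynamic_model()],
#'   [simulate_dynamic()]
#' @export
dynamic_model <- function(baseline_tp, baseline_td, baseline_os,
                          response_time, loss_of_response_time,
                          response_prob, hr_table, inflection = 3) {
  stopifnot(inherits(baseline_tp, "weibull_params"),
            inherits(baseline_td, "weibull_params"),
            inherits(baseline_os, "weibull_params"),
            inherits(response_time, "lognormal_params"),
            inherits(loss_of_response_time, "gompertz_params"),
            inherits(hr_table, "hr_table"),
            is.numeric(inflection), length(inflection) == 1L, inflection > 0)
  structure(list(
    baseline_tp = baseline_tp, baseline_td = baseline_td,
    baseline_os = baseline_os,
    response_time = response_time,
    loss_of_response_time = loss_of_response_time,
    response_prob = .resp_prob_matrix(response_prob),
    hr_table = hr_table,
    inflection = as.numeric(inflection)), class = "dynamic_model")
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat("Dynamic survival model\n")
  cat("  baseline TTP:     "); print(x$baseline_tp)
  cat("  baseline TTD:     "); print(x$baseline_td)
  cat("  baseline TTDeath: "); print(x$baseline_os)
  cat(sprintf("  time to response: log-normal(meanlog %.3g, sdlog %.3g)\n",
              x$response_time$meanlog, x$response_time$sdlog))
  cure <- gompertz_cure_fraction(x$loss_of_response_time)
  cat(sprintf("  time to loss:     Gompertz(shape %.3g, rate %.3g)%s\n",
              x$loss_of_response_time$shape, x$loss_of_response_time$rate,
              if (cure > 0) sprintf(" [never-lose fraction %.1f%%]",
                                    100 * cure) else ""))
  cat(sprintf("  response prob:    treatment %.3g / comparator %.3g (poor stratum)\n",
              x$response_prob["treatment", "poor"],
              x$response_prob["comparator", "poor"]))
  cat(sprintf("  inflection:       %.3g months\n", x$inflection))
  print(x$hr_table)
  invisible(x)
}

#' Published-analysis hazard-ratio table
#'
#' The multivariate hazard ratios reported by the motivating trial analysis
#' (objective response, loss of response, MSKCC risk and piecewise treatment
#' effects on progression, discontinuation and death). Used as the default
#' simulation truth of the synthetic generator.
#'
#' @return An [hr_table()].
#' @export
default_hr_table <- function() {
  hr_table(
    progression = c(response = 0.40, favorable = 0.63, intermediate = 0.79,
                    treat_early = 1.19, treat_late = 0.88),
    discontinuation = c(response = 0.18, post_response = 1.34,
                        favorable = 0.64, intermediate = 0.79, treat = 0.73),
    death = c(response = 0.06, post_response = 0.49, favorable = 0.29,
              intermediate = 0.61, treat_early = 0.50, treat_late = 0.94))
}

#' Default dynamic model (shipped calibration)
#'
#' Reads the versioned configuration shipped with the package
#' (`inst/extdata/default_model.json`). Hazard ratios and response
#' probabilities are the published trial estimates; the Weibull baselines
#' and response-time/loss-of-response submodels are package calibration
#' values chosen so that simulated medians sit near the published
#' arm-level medians (the underlying patient-level fits are not public).
#'
#' @return A [dynamic_model()].
#' @export
default_dynamic_model <- function() {
  path <- system.file("extdata", "default_model.json", package = "dicesurv")
  if (!nzchar(path)) stop("default_model.json not found")
  read_model_json(path)
}

#' Trial design for the synthetic generator
#'
#' @param n_per_arm Number of patients per arm; a single count or a named
#'   vector `c(treatment=, comparator=)`.
#' @param mskcc_probs Probabilities of the three MSKCC risk groups, named
#'   `favorable`, `intermediate`, `poor`; must sum to 1 (within 1e-12).
#' @param accrual_months Length of the uniform accrual window (months,
#'   >= 0). Administrative censoring per patient is
#'   `min_followup_months + U(0, accrual_months)`.
#' @param min_followup_months Administrative minimum follow-up (months, > 0).
#' @param response_prob Optional override of the model's latent responder
#'   probabilities (same forms as in [dynamic_model()]); `NULL` uses the
#'   model's values.
#' @param seed Integer random seed; each patient receives a substream
#'   derived deterministically from `(seed, id)`, so enlarging the cohort
#'   does not reshuffle earlier patients.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = c(treatment = 410, comparator = 411),
                         mskcc_probs = c(favorable = 0.35,
                                         intermediate = 0.49, poor = 0.16),
                         accrual_months = 17, min_followup_months = 14,
                         response_prob = NULL, seed = 1L) {
  if (length(n_per_arm) == 1L)
    n_per_arm <- c(treatment = n_per_arm, comparator = n_per_arm)
  if (is.null(names(n_per_arm)) || !all(.ARM_LEVELS %in% names(n_per_arm)))
    stop("n_per_arm must be a count or named c(treatment=, comparator=)")
  n_per_arm <- n_per_arm[c("treatment", "comparator")]
  if (any(n_per_arm < 1) || any(n_per_arm != round(n_per_arm)))
    stop("n_per_arm must be integer counts >= 1")
  if (is.null(names(mskcc_probs)) ||
      !all(c("favorable", "intermediate", "poor") %in% names(mskcc_probs)))
    stop("mskcc_probs must be named favorable/intermediate/poor")
  mskcc_probs <- mskcc_probs[c("favorable", "intermediate", "poor")]
  if (any(mskcc_probs < 0) || abs(sum(mskcc_probs) - 1) > 1e-12)
    stop("mskcc_probs must be non-negative and sum to 1 (within 1e-12)")
  if (!is.numeric(accrual_months) || accrual_months < 0)
    stop("accrual_months must be >= 0")
  if (!is.numeric(min_followup_months) || min_followup_months <= 0)
    stop("min_followup_months must be > 0")
  if (!is.null(response_prob)) response_prob <- .resp_prob_matrix(response_prob)
  structure(list(n_per_arm = n_per_arm, mskcc_probs = mskcc_probs,
                 accrual_months = as.numeric(accrual_months),
                 min_followup_months = as.numeric(min_followup_months),
                 response_prob = response_prob, seed = as.integer(seed)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(paste0("Trial design: %d treatment / %d comparator; MSKCC ",
                     "f/i/p = %.2f/%.2f/%.2f;\n  accrual %.3g mo, minimum ",
                     "follow-up %.3g mo, seed %d\n"),
              x$n_per_arm["treatment"], x$n_per_arm["comparator"],
              x$mskcc_probs["favorable"], x$mskcc_probs["intermediate"],
              x$mskcc_probs["poor"], x$accrual_months,
              x$min_followup_months, x$seed))
  invisible(x)
}

#' Read / write a dynamic model as JSON
#'
#' Serializes a [dynamic_model()] (baselines, submodels, response
#' probabilities, hazard-ratio table, inflection) to a JSON configuration
#' file, the exchange format between the estimation stage and the
#' microsimulation engine.
#'
#' @param model A [dynamic_model()].
#' @param path File path.
#' @return `read_model_json()` returns a [dynamic_model()];
#'   `write_model_json()` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "dynamic_model"))
  obj <- list(
    convention = "Weibull S(t) = exp(-(t/scale)^shape); months",
    baseline_tp = unclass(model$baseline_tp),
    baseline_td = unclass(model$baseline_td),
    baseline_os = unclass(model$baseline_os),
    response_time = unclass(model$response_time),
    loss_of_response_time = unclass(model$loss_of_response_time),
    response_prob = apply(model$response_prob, 1L, as.list, simplify = FALSE),
    hr_table = lapply(unclass(model$hr_table), as.list),
    inflection = model$inflection)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rp <- do.call(rbind, lapply(.ARM_LEVELS, function(a)
    unlist(obj$response_prob[[a]])[.MSKCC_LEVELS]))
  rownames(rp) <- .ARM_LEVELS
  dynamic_model(
    baseline_tp = weibull_params(obj$baseline_tp$shape, obj$baseline_tp$scale),
    baseline_td = weibull_params(obj$baseline_td$shape, obj$baseline_td$scale),
    baseline_os = weibull_params(obj$baseline_os$shape, obj$baseline_os$scale),
    response_time = lognormal_params(obj$response_time$meanlog,
                                     obj$response_time$sdlog),
    loss_of_response_time = gompertz_params(obj$loss_of_response_time$shape,
                                            obj$loss_of_response_time$rate),
    response_prob = rp,
    hr_table = hr_table(progression = unlist(obj$hr_table$progression),
                        discontinuation = unlist(obj$hr_table$discontinuation),
                        death = unlist(obj$hr_table$death)),
    inflection = obj$inflection %||% 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
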