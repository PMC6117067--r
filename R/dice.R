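# Patient-level DICE (discretely integrated condition event)
# microsimulation. Conditions (response state, treatment period) are
# updated at scheduled events; because each patient's full multiplier
# schedule is known once the response and loss times are drawn, every
# endpoint time is realized by a single piecewise cumulative-hazard
# inversion — continuous time, no per-cycle discretization error.

#' Microsimulation configuration
#'
#' @param n_patients Simulated patients per arm (>= 1).
#' @param horizon Projection horizon in months (default 300 = 25 years).
#' @param seed Integer seed (per-patient substreams as in
#'   [generate_trial()]).
#' @param landmark_months Landmark times for summaries (default 36 and
#'   60 months, i.e. 3- and 5-year survival); must not exceed the horizon.
#' @param mskcc_probs Risk-group mix of the simulated population; default
#'   the trial-design default mix.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 10000L, horizon = 300,
                              seed = 1L, landmark_months = c(36, 60),
                              mskcc_probs = c(favorable = 0.35,
                                              intermediate = 0.49,
                                              poor = 0.16)) {
  stopifnot(n_patients >= 1, horizon > 0, all(landmark_months <= horizon),
            abs(sum(mskcc_probs) - 1) < 1e-12)
  structure(list(n_patients = as.integer(n_patients),
                 horizon = as.numeric(horizon), seed = as.integer(seed),
                 landmark_months = landmark_months,
                 mskcc_probs = mskcc_probs[c("favorable", "intermediate",
                                             "poor")]),
            class = "simulation_config")
}

.histories_frame <- function(n, arms) {
  data.frame(id = seq_len(n), arm = factor(arms, levels = .ARM_LEVELS),
             mskcc = factor(rep(NA_character_, n), levels = .MSKCC_LEVELS),
             responded = logical(n), t_response = numeric(n),
             t_loss_response = numeric(n), t_progression = numeric(n),
             t_discontinuation = numeric(n), t_death = numeric(n))
}

#' Simulate long-horizon event histories under the dynamic model
#'
#' Per patient: draw arm, MSKCC group and latent responder status; for
#' responders draw time to response (log-normal) and time to loss
#' (Gompertz, possibly infinite); assemble per-endpoint hazard-multiplier
#' schedules from the hazard-ratio table (response-state switches at
#' response/loss, treatment-period switch at the inflection, MSKCC and
#' arm multipliers constant) and realize each endpoint by piecewise
#' cumulative-hazard inversion. Response gating and the
#' loss-of-response-manifests-as-progression rule are identical to the
#' trial generator. Times are stored uncensored (possibly `Inf` under an
#' improper schedule); truncation to the horizon happens in
#' [summarize_histories()].
#'
#' @param model A [dynamic_model()].
#' @param config A [simulation_config()].
#' @return An `event_histories` data frame with per-patient arm, risk
#'   group, response trajectory and latent endpoint times; attribute
#'   `"horizon"` carries the projection horizon.
#' @export
simulate_dynamic <- function(model, config) {
  stopifnot(inherits(model, "dynamic_model"),
            inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n <- 2L * config$n_patients
  arms <- rep(c("treatment", "comparator"), each = config$n_patients)
  out <- .histories_frame(n, arms)
  mskcc <- character(n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(config$seed, i, salt = 2))
    p <- .draw_patient(arms[i], config$mskcc_probs, model)
    mskcc[i] <- p$mskcc
    out$responded[i] <- p$responded
    out$t_response[i] <- p$t_response
    out$t_loss_response[i] <- p$t_loss_response
    out$t_progression[i] <- p$t_progression
    out$t_discontinuation[i] <- p$t_discontinuation
    out$t_death[i] <- p$t_death
  }
  out$mskcc <- factor(mskcc, levels = .MSKCC_LEVELS)
  attr(out, "horizon") <- config$horizon
  class(out) <- c("event_histories", "data.frame")
  out
}

#' Simulate event histories under the standard parametric model
#'
#' Endpoint times are drawn independently per arm from the fitted
#' single-distribution models (no response process, no covariate
#' dynamics), by inverse-CDF sampling with per-patient substreams.
#'
#' @param fits A nested list `fits[[arm]][[endpoint]]` of
#'   `parametric_fit` objects, arms `"treatment"` and `"comparator"`,
#'   endpoints `"progression"`, `"discontinuation"`, `"death"` (missing
#'   endpoints raise an error).
#' @param config A [simulation_config()].
#' @return An `event_histories` data frame (response columns inert).
#' @export
simulate_standard <- function(fits, config) {
  stopifnot(inherits(config, "simulation_config"))
  for (a in .ARM_LEVELS) for (ep in .ENDPOINTS) {
    if (!inherits(fits[[a]][[ep]], "parametric_fit"))
      stop("missing parametric fit for ", a, " / ", ep)
  }
  qf <- lapply(fits, function(armfits) lapply(armfits, quantile_function))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n <- 2L * config$n_patients
  arms <- rep(c("treatment", "comparator"), each = config$n_patients)
  out <- .histories_frame(n, arms)
  out$t_response <- NA_real_
  out$t_loss_response <- NA_real_
  for (i in seq_len(n)) {
    set.seed(.substream_seed(config$seed, i, salt = 3))
    u <- stats::runif(3)
    a <- arms[i]
    out$t_progression[i] <- qf[[a]]$progression(u[1])
    out$t_discontinuation[i] <- qf[[a]]$discontinuation(u[2])
    out$t_death[i] <- qf[[a]]$death(u[3])
  }
  attr(out, "horizon") <- config$horizon
  class(out) <- c("event_histories", "data.frame")
  out
}

.history_sample <- function(histories, endpoint, arm, horizon,
                            cap_at_death = TRUE) {
  idx <- histories$arm == arm
  t <- switch(endpoint, progression = histories$t_progression,
              discontinuation = histories$t_discontinuation,
              death = histories$t_death)[idx]
  if (cap_at_death && endpoint != "death")
    t <- pmin(t, histories$t_death[idx])
  ev <- as.integer(t <= horizon)
  survival_sample(pmin(t, horizon), ev)
}

#' Summarize simulated event histories
#'
#' Per endpoint and arm: Kaplan-Meier median (`NA` when not reached
#' within the horizon), restricted mean over the horizon (area under the
#' simulated survival step function), and landmark survival
#' probabilities, with optional Monte-Carlo standard errors from a
#' patient-level bootstrap.
#'
#' @param histories An `event_histories` data frame.
#' @param config The [simulation_config()] used (horizon and landmarks).
#' @param cap_at_death If `TRUE` (default) progression and
#'   discontinuation times are capped at death, which then counts as an
#'   event (composite endpoint, matching trial-style reporting); if
#'   `FALSE` the endpoint's marginal distribution is summarized.
#' @param n_boot Bootstrap resamples for standard errors (default 0 =
#'   none; 200 is a reasonable precision/runtime compromise).
#' @return An `outcome_summary` data frame: endpoint, arm, n, events,
#'   median, rmst, one `s<landmark>` column per landmark, and `_se`
#'   columns when `n_boot > 0`.
#' @export
summarize_histories <- function(histories, config, cap_at_death = TRUE,
                                n_boot = 0L) {
  stopifnot(inherits(histories, "event_histories"),
            inherits(config, "simulation_config"))
  horizon <- config$horizon
  one <- function(h, endpoint, arm) {
    s <- .history_sample(h, endpoint, arm, horizon, cap_at_death)
    km <- km_estimate(s)
    c(n = length(s$times), events = sum(s$events),
      median = km_median(km), rmst = km_rmst(km, horizon),
      stats::setNames(km_surv_at(km, config$landmark_months),
                      paste0("s", config$landmark_months)))
  }
  rows <- list()
  for (ep in .ENDPOINTS) for (a in .ARM_LEVELS) {
    if (!any(histories$arm == a)) next
    est <- one(histories, ep, a)
    row <- data.frame(endpoint = ep, arm = a, t(est))
    if (n_boot > 0) {
      idx_arm <- which(histories$arm == a)
      boots <- replicate(n_boot, {
        bi <- sample(idx_arm, length(idx_arm), replace = TRUE)
        one(histories[c(bi, which(histories$arm != a)), ], ep, a)
      })
      se <- apply(boots, 1, stats::sd, na.rm = TRUE)
      names(se) <- paste0(names(est), "_se")
      row <- cbind(row, t(se[-(1:2)]))
    }
    rows[[paste(ep, a)]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "horizon") <- horizon
  attr(out, "cap_at_death") <- cap_at_death
  class(out) <- c("outcome_summary", "data.frame")
  out
}
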