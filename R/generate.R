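# Synthetic two-arm trial generator.
#
# Each patient owns a deterministic RNG substream derived from (seed, id),
# and always consumes the same number of draws, so cohort growth never
# reshuffles earlier patients. Endpoint times are realized by inverting the
# integrated hazard of a Weibull baseline under the patient's full
# piecewise multiplier schedule (MSKCC risk x treatment period x response
# state). A latent responder whose sampled response time is not reached
# before progression or death is demoted to nonresponder; the demoted
# patient's endpoint times are re-inverted under the nonresponse-only
# schedule *reusing the same uniform draws*, which leaves the law on
# [0, t_response) untouched and replaces the continuation beyond it with
# the correct nonresponse law.

.substream_seed <- function(seed, id, salt = 0) {
  s <- ((abs(as.numeric(seed)) %% 2147483647) * 48271) %% 2147483647
  s <- (s + as.numeric(id) * 9973 + as.numeric(salt) * 7919) %% 2147483647
  as.integer(s)
}

# Piecewise multiplier schedule for one endpoint and one covariate path.
# t_resp = Inf encodes "never responds". Returns list(starts, mults).
.endpoint_schedule <- function(endpoint, arm, mskcc, t_resp, t_loss,
                               hr_tab, inflection) {
  v <- hr_tab[[endpoint]]
  m_msk <- switch(mskcc, favorable = v[["favorable"]],
                  intermediate = v[["intermediate"]], poor = 1)
  piecewise_trt <- endpoint != "discontinuation"
  breaks <- 0
  if (arm == "treatment" && piecewise_trt) breaks <- c(breaks, inflection)
  if (is.finite(t_resp)) breaks <- c(breaks, t_resp)
  if (endpoint != "progression" && is.finite(t_resp) && is.finite(t_loss))
    breaks <- c(breaks, t_loss)
  breaks <- sort(unique(breaks))
  mults <- vapply(breaks, function(s) {
    m_trt <- if (arm != "treatment") 1
      else if (!piecewise_trt) v[["treat"]]
      else if (s < inflection) v[["treat_early"]] else v[["treat_late"]]
    m_state <- if (s >= t_resp && (endpoint == "progression" ||
                                   !is.finite(t_loss) || s < t_loss))
        v[["response"]]
      else if (endpoint != "progression" && is.finite(t_loss) && s >= t_loss)
        v[["post_response"]]
      else 1
    m_msk * m_trt * m_state
  }, numeric(1))
  list(starts = breaks, mults = mults)
}

.baseline_for <- function(model, endpoint) {
  switch(endpoint, progression = model$baseline_tp,
         discontinuation = model$baseline_td, death = model$baseline_os)
}

.invert_endpoint <- function(model, endpoint, arm, mskcc, t_resp, t_loss, u) {
  b <- .baseline_for(model, endpoint)
  sch <- .endpoint_schedule(endpoint, arm, mskcc, t_resp, t_loss,
                            model$hr_table, model$inflection)
  .piecewise_invert(-log(u), b$shape, b$scale, sch$starts, sch$mults)
}

# Consumes exactly 8 uniforms from the current RNG stream and returns the
# latent outcome of one patient. Response gating: the response state is
# entered only if t_response precedes both progression and death; for
# responders, loss of response manifests as progression.
.draw_patient <- function(arm, mskcc_probs, model) {
  u <- stats::runif(8)
  mskcc <- c("favorable", "intermediate", "poor")[
    findInterval(u[1], cumsum(mskcc_probs)) + 1L]
  p_resp <- model$response_prob[arm, mskcc]
  latent <- u[2] < p_resp
  t_resp <- stats::qlnorm(u[3], model$response_time$meanlog,
                          model$response_time$sdlog)
  d_loss <- flexsurv::qgompertz(u[4], shape = model$loss_of_response_time$shape,
                                rate = model$loss_of_response_time$rate)
  out <- .realize_patient(arm, mskcc, latent, t_resp, t_resp + d_loss,
                          u[5], u[6], u[7], model)
  out$u_accrual <- u[8]
  out$latent_responder <- latent
  out
}

.realize_patient <- function(arm, mskcc, latent, t_resp, t_loss,
                             u_tp, u_td, u_os, model) {
  if (latent) {
    tp_r <- .invert_endpoint(model, "progression", arm, mskcc, t_resp, t_loss, u_tp)
    os_r <- .invert_endpoint(model, "death", arm, mskcc, t_resp, t_loss, u_os)
    responded <- t_resp < min(tp_r, os_r)
  } else responded <- FALSE
  if (responded) {
    td <- .invert_endpoint(model, "discontinuation", arm, mskcc, t_resp, t_loss, u_td)
    tp_via_loss <- t_loss < tp_r
    tp <- min(tp_r, t_loss)
    os <- os_r
  } else {
    tp <- .invert_endpoint(model, "progression", arm, mskcc, Inf, Inf, u_tp)
    td <- .invert_endpoint(model, "discontinuation", arm, mskcc, Inf, Inf, u_td)
    os <- .invert_endpoint(model, "death", arm, mskcc, Inf, Inf, u_os)
    t_resp <- NA_real_
    t_loss <- NA_real_
    tp_via_loss <- FALSE
  }
  list(mskcc = mskcc, responded = responded, t_response = t_resp,
       t_loss_response = t_loss, t_progression = tp,
       t_discontinuation = td, t_death = os, tp_via_loss = tp_via_loss)
}

#' Generate a synthetic two-arm trial
#'
#' Simulates patient-level data with the statistical structure the dynamic
#' analysis assumes: MSKCC risk strata, latent responders with log-normal
#' time to response and Gompertz (possibly improper) time to loss of
#' response, endpoint times drawn from reference Weibull baselines under
#' piecewise hazard-ratio schedules, and administrative censoring at a
#' minimum follow-up plus a uniform accrual offset.
#'
#' @param design A [trial_design()].
#' @param model A [dynamic_model()] acting as simulation truth.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A data frame of patient records (one row per patient) with
#'   latent columns (`t_progression`, `t_discontinuation`, `t_death`,
#'   `t_response`, `t_loss_response`, `tp_via_loss`, `c_admin`) and
#'   observed columns (`obs_tp`/`ev_tp`, `obs_td`/`ev_td`,
#'   `obs_os`/`ev_os`). The attribute `"response_rates"` reports nominal
#'   latent, realized (post-gating) and observed response fractions per
#'   arm; realized rates sit slightly below nominal because response must
#'   be achieved while progression- and death-free.
#' @examples
#' design <- trial_design(n_per_arm = 50, seed = 7)
#' trial <- generate_trial(design, default_dynamic_model())
#' table(trial$arm, trial$mskcc)
#' @export
generate_trial <- function(design, model, seed = design$seed) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "dynamic_model"))
  if (!is.null(design$response_prob)) {
    model$response_prob <- design$response_prob
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  n_t <- design$n_per_arm[["treatment"]]
  n_c <- design$n_per_arm[["comparator"]]
  n <- n_t + n_c
  arm <- rep(c("treatment", "comparator"), c(n_t, n_c))
  cols <- list(mskcc = character(n), latent_responder = logical(n),
               responded = logical(n), t_response = numeric(n),
               t_loss_response = numeric(n), t_progression = numeric(n),
               t_discontinuation = numeric(n), t_death = numeric(n),
               tp_via_loss = logical(n), c_admin = numeric(n))
  for (i in seq_len(n)) {
    set.seed(.substream_seed(seed, i))
    p <- .draw_patient(arm[i], design$mskcc_probs, model)
    cols$mskcc[i] <- p$mskcc
    cols$latent_responder[i] <- p$latent_responder
    cols$responded[i] <- p$responded
    cols$t_response[i] <- p$t_response
    cols$t_loss_response[i] <- p$t_loss_response
    cols$t_progression[i] <- p$t_progression
    cols$t_discontinuation[i] <- p$t_discontinuation
    cols$t_death[i] <- p$t_death
    cols$tp_via_loss[i] <- p$tp_via_loss
    cols$c_admin[i] <- design$min_followup_months +
      p$u_accrual * design$accrual_months
  }
  rec <- data.frame(id = seq_len(n), arm = factor(arm, levels = .ARM_LEVELS),
                    mskcc = factor(cols$mskcc, levels = .MSKCC_LEVELS),
                    latent_responder = cols$latent_responder,
                    responded = cols$responded,
                    t_response = cols$t_response,
                    t_loss_response = cols$t_loss_response,
                    t_progression = cols$t_progression,
                    t_discontinuation = cols$t_discontinuation,
                    t_death = cols$t_death,
                    tp_via_loss = cols$tp_via_loss,
                    c_admin = cols$c_admin)
  rec <- apply_censoring(rec, design)
  rates <- do.call(rbind, lapply(.ARM_LEVELS, function(a) {
    idx <- rec$arm == a
    data.frame(arm = a,
               nominal = mean(model$response_prob[a, as.character(rec$mskcc[idx])]),
               realized = mean(rec$responded[idx]),
               observed = mean(rec$responded[idx] &
                               rec$t_response[idx] <= rec$c_admin[idx],
                               na.rm = TRUE))
  }))
  attr(rec, "response_rates") <- rates
  attr(rec, "inflection") <- model$inflection
  class(rec) <- c("patient_records", "data.frame")
  rec
}

#' Apply administrative censoring and death truncation
#'
#' Fills the observed `(time, event)` pair per endpoint from the latent
#' times: every endpoint is censored at the administrative time `c_admin`;
#' death additionally truncates (censors) observed progression and
#' discontinuation, while progression and discontinuation truncate neither
#' each other nor death (semi-competing structure, endpoints reported
#' separately).
#'
#' @param records Patient records with latent time columns and `c_admin`
#'   (if `c_admin` is absent it is drawn from the design's accrual window
#'   using the per-patient substream).
#' @param design A [trial_design()]; only needed to draw a missing
#'   `c_admin`.
#' @return The records with `obs_tp`, `ev_tp`, `obs_td`, `ev_td`,
#'   `obs_os`, `ev_os` columns (re)computed.
#' @export
apply_censoring <- function(records, design = NULL) {
  if (is.null(records$c_admin) || all(is.na(records$c_admin))) {
    if (is.null(design)) stop("need a trial_design to draw c_admin")
    u <- vapply(records$id, function(i) {
      set.seed(.substream_seed(design$seed, i, salt = 1))
      stats::runif(1)
    }, numeric(1))
    records$c_admin <- design$min_followup_months + u * design$accrual_months
  }
  dlim <- pmin(records$t_death, records$c_admin)
  records$obs_tp <- pmin(records$t_progression, dlim)
  records$ev_tp <- as.integer(records$t_progression <= dlim)
  records$obs_td <- pmin(records$t_discontinuation, dlim)
  records$ev_td <- as.integer(records$t_discontinuation <= dlim)
  records$obs_os <- pmin(records$t_death, records$c_admin)
  records$ev_os <- as.integer(records$t_death <= records$c_admin)
  records
}

#' Write / read patient-level trial data as CSV
#'
#' The exchange schema is one row per patient with columns `id, arm, mskcc,
#' latent_responder, t_response, t_loss_response, obs_tp, ev_tp, obs_td,
#' ev_td, obs_os, ev_os, c_admin`; months as decimals, absent times as
#' empty fields, `+Inf` (a durable responder who never loses response) as
#' `"inf"`. `latent_responder` in the file is the post-gating responder
#' flag, i.e. `TRUE` exactly when `t_response` is present.
#'
#' @param records Patient records from [generate_trial()].
#' @param path File path.
#' @return `read_trial_csv()` returns a `patient_records` data frame
#'   (loss-driven progression events are reconstructed from
#'   `obs_tp == t_loss_response`); `write_trial_csv()` returns `path`
#'   invisibly.
#' @export
write_trial_csv <- function(records, path) {
  num <- function(x) {
    out <- ifelse(is.na(x), "", ifelse(is.infinite(x), "inf",
                                       format(x, digits = 10)))
    out
  }
  df <- data.frame(id = records$id, arm = as.character(records$arm),
                   mskcc = as.character(records$mskcc),
                   latent_responder = as.integer(records$responded),
                   t_response = num(records$t_response),
                   t_loss_response = num(records$t_loss_response),
                   obs_tp = num(records$obs_tp), ev_tp = records$ev_tp,
                   obs_td = num(records$obs_td), ev_td = records$ev_td,
                   obs_os = num(records$obs_os), ev_os = records$ev_os,
                   c_admin = num(records$c_admin))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- function(x) {
    x <- as.character(x)
    out <- suppressWarnings(as.numeric(ifelse(x == "inf", "Inf", x)))
    out[x == ""] <- NA_real_
    out
  }
  rec <- data.frame(id = df$id,
                    arm = factor(df$arm, levels = .ARM_LEVELS),
                    mskcc = factor(df$mskcc, levels = .MSKCC_LEVELS),
                    latent_responder = df$latent_responder == 1,
                    responded = df$latent_responder == 1,
                    t_response = num(df$t_response),
                    t_loss_response = num(df$t_loss_response),
                    obs_tp = num(df$obs_tp), ev_tp = df$ev_tp,
                    obs_td = num(df$obs_td), ev_td = df$ev_td,
                    obs_os = num(df$obs_os), ev_os = df$ev_os,
                    c_admin = num(df$c_admin))
  rec$tp_via_loss <- !is.na(rec$t_loss_response) & rec$ev_tp == 1 &
    abs(rec$obs_tp - rec$t_loss_response) < 1e-9
  class(rec) <- c("patient_records", "data.frame")
  rec
}
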