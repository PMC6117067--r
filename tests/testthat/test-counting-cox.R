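one_patient_records <- function(...) {
  # minimal record constructor for hand-built counting-process cases
  defaults <- list(responded = FALSE, t_response = NA_real_,
                   t_loss_response = NA_real_, tp_via_loss = FALSE,
                   arm = "treatment", mskcc = "poor")
  args <- utils::modifyList(defaults, list(...))
  df <- data.frame(id = seq_along(args$obs_os), arm = factor(args$arm,
                   levels = c("comparator", "treatment")),
                   mskcc = factor(args$mskcc,
                                  levels = c("poor", "favorable",
                                             "intermediate")),
                   responded = args$responded,
                   t_response = args$t_response,
                   t_loss_response = args$t_loss_response,
                   tp_via_loss = args$tp_via_loss,
                   obs_tp = args$obs_tp %||% args$obs_os,
                   ev_tp = args$ev_tp %||% args$ev_os,
                   obs_td = args$obs_td %||% args$obs_os,
                   ev_td = args$ev_td %||% args$ev_os,
                   obs_os = args$obs_os, ev_os = args$ev_os,
                   c_admin = args$c_admin %||% rep(100, length(args$obs_os)))
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("episode splitting follows the covariate timeline", {
  # nonresponder with an event at 2 months: a single early episode
  rec <- one_patient_records(obs_os = 2, ev_os = 1L)
  cp <- build_counting_process(rec, "death", inflection = 3)
  expect_identical(nrow(cp), 1L)
  expect_equal(c(cp$start, cp$stop), c(0, 2))
  expect_identical(cp$event, 1L)
  expect_identical(as.character(cp$response_state), "nonresponse")
  expect_identical(as.character(cp$period), "early")

  # responder at 4 months censored at 14: split at 3 and 4
  rec2 <- one_patient_records(obs_os = 14, ev_os = 0L, responded = TRUE,
                              t_response = 4, t_loss_response = Inf)
  cp2 <- build_counting_process(rec2, "death", inflection = 3)
  expect_equal(cp2$start, c(0, 3, 4))
  expect_equal(cp2$stop, c(3, 4, 14))
  expect_identical(as.character(cp2$response_state),
                   c("nonresponse", "nonresponse", "response"))
  expect_identical(as.character(cp2$period), c("early", "late", "late"))
  expect_identical(cp2$event, c(0L, 0L, 0L))

  # loss of response adds a post-response episode for death
  rec3 <- one_patient_records(obs_os = 20, ev_os = 1L, responded = TRUE,
                              t_response = 2, t_loss_response = 9)
  cp3 <- build_counting_process(rec3, "death", inflection = 3)
  expect_equal(cp3$start, c(0, 2, 3, 9))
  expect_equal(cp3$stop, c(2, 3, 9, 20))
  expect_identical(as.character(cp3$response_state),
                   c("nonresponse", "response", "response", "post_response"))
  expect_identical(cp3$event, c(0L, 0L, 0L, 1L))
})

test_that("loss-driven progression ends risk without a hazard event", {
  rec <- one_patient_records(obs_os = 20, ev_os = 0L, responded = TRUE,
                             t_response = 2, t_loss_response = 9,
                             obs_tp = 9, ev_tp = 1L, tp_via_loss = TRUE,
                             c_admin = 20)
  cp <- build_counting_process(rec, "progression", inflection = 3)
  # progression has no post-response state; follow-up ends at the loss
  expect_equal(max(cp$stop), 9)
  expect_identical(sum(cp$event), 0L)
  expect_false("post_response" %in% as.character(cp$response_state))
  # a spontaneous progression in the response state stays an event
  rec2 <- one_patient_records(obs_os = 20, ev_os = 0L, responded = TRUE,
                              t_response = 2, t_loss_response = 30,
                              obs_tp = 7, ev_tp = 1L, tp_via_loss = FALSE,
                              c_admin = 20)
  cp2 <- build_counting_process(rec2, "progression", inflection = 3)
  expect_identical(sum(cp2$event), 1L)
  expect_equal(cp2$stop[which(cp2$event == 1L)], 7)
})

test_that("exposure is conserved across episodes of a cohort", {
  tr <- make_trial(n_per_arm = 500, seed = 41)
  for (ep in c("progression", "discontinuation", "death")) {
    cp <- build_counting_process(tr, ep)
    exp_col <- switch(ep, progression = "obs_tp",
                      discontinuation = "obs_td", death = "obs_os")
    got <- tapply(cp$stop - cp$start, cp$id, sum)
    want <- tr[[exp_col]][match(as.integer(names(got)), tr$id)]
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
    # episodes contiguous from 0, at most one event per subject
    first <- tapply(cp$start, cp$id, min)
    expect_true(all(first == 0))
    expect_true(all(tapply(cp$event, cp$id, sum) <= 1))
  }
})

test_that("Cox coefficients match brute-force partial-likelihood maximization", {
  # two groups, no ties: events at 1, 3 (group A), 2, 4 (group B)
  df <- data.frame(id = 1:4, start = 0, stop = c(1, 3, 2, 4), event = 1L,
                   response_state = factor("nonresponse",
                     levels = c("nonresponse", "response", "post_response")),
                   mskcc = factor("poor"),
                   arm = factor(c("treatment", "treatment", "comparator",
                                  "comparator"),
                                levels = c("comparator", "treatment")),
                   period = factor("early", levels = c("early", "late")))
  class(df) <- c("counting_process", "data.frame")
  fit <- fit_cox(df, covariates = "treatment",
                 treatment_effect = "constant", ties = "breslow")
  want <- oracle_cox_coef(df$start, df$stop, df$event,
                          as.integer(df$arm == "treatment"))
  expect_equal(fit$table$coef, want, tolerance = 1e-6)

  # a time-split fixture with three covariates, against the same oracle
  # (continuous synthetic times: no event-time ties, so Breslow = exact)
  tr <- make_trial(n_per_arm = 40, seed = 43)
  cp <- build_counting_process(tr, "death")
  X <- cbind(fav = as.integer(cp$mskcc == "favorable"),
             int = as.integer(cp$mskcc == "intermediate"),
             trt = as.integer(cp$arm == "treatment"))
  got <- fit_cox(cp, covariates = c("mskcc", "treatment"),
                 treatment_effect = "constant", ties = "breslow")
  want2 <- oracle_cox_coef(cp$start, cp$stop, cp$event, X)
  got_beta <- got$table$coef[match(c("favorable", "intermediate", "treat"),
                                   got$table$term)]
  expect_equal(got_beta, want2, tolerance = 1e-5)
})

test_that("degenerate covariates are rejected as collinear", {
  tr <- make_trial(n_per_arm = 50, seed = 44,
                   response_prob = c(treatment = 0, comparator = 0))
  cp <- build_counting_process(tr, "death")
  expect_error(fit_cox(cp, covariates = "response_state"), "no variation")
  one_arm <- cp[cp$arm == "treatment", ]
  expect_error(fit_cox(one_arm, covariates = "treatment"), "no variation")
})

test_that("partial likelihood is invariant to episode over-splitting", {
  tr <- make_trial(n_per_arm = 150, seed = 45)
  cp <- build_counting_process(tr, "death")
  fit1 <- fit_cox(cp)
  # insert an extra boundary at 1.7 months with unchanged covariates
  cut <- 1.7
  straddle <- cp$start < cut & cp$stop > cut
  left <- cp[straddle, ]; left$stop <- cut; left$event <- 0L
  right <- cp[straddle, ]; right$start <- cut
  cp2 <- rbind(cp[!straddle, ], left, right)
  class(cp2) <- class(cp)
  attr(cp2, "endpoint") <- attr(cp, "endpoint")
  fit2 <- fit_cox(cp2)
  expect_equal(fit1$table$coef, fit2$table$coef, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("with baseline-only covariates, split and unsplit data agree", {
  tr <- make_trial(n_per_arm = 150, seed = 46,
                   response_prob = c(treatment = 0, comparator = 0))
  cp_split <- build_counting_process(tr, "death")
  cp_flat <- data.frame(id = tr$id, start = 0, stop = tr$obs_os,
                        event = tr$ev_os,
                        response_state = factor("nonresponse",
                          levels = levels(cp_split$response_state)),
                        mskcc = tr$mskcc, arm = tr$arm,
                        period = factor("early",
                                        levels = c("early", "late")))
  class(cp_flat) <- class(cp_split)
  f1 <- fit_cox(cp_split, covariates = c("mskcc", "treatment"),
                treatment_effect = "constant")
  f2 <- fit_cox(cp_flat, covariates = c("mskcc", "treatment"),
                treatment_effect = "constant")
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-8)
})

test_that("treating response as a baseline covariate inflates its benefit", {
  # immortal-time bias: ever-responders must have survived long enough to
  # respond, so a baseline coding exaggerates the protective death effect.
  # The demonstration uses a null response effect: the time-dependent
  # estimate is ~1 while the baseline coding shows spurious protection.
  m <- unit_hr_model(response_prob = c(treatment = 0.25, comparator = 0.05))
  tr <- make_trial(n_per_arm = 1500, seed = 47, model = m)
  cp <- build_counting_process(tr, "death")
  td_fit <- fit_cox(cp)
  hr_td <- td_fit$table$hr[td_fit$table$term == "response"]
  flat <- data.frame(id = tr$id, start = 0, stop = tr$obs_os,
                     event = tr$ev_os,
                     response_state = factor(
                       ifelse(tr$responded, "response", "nonresponse"),
                       levels = c("nonresponse", "response",
                                  "post_response")),
                     mskcc = tr$mskcc, arm = tr$arm,
                     period = factor("early", levels = c("early", "late")))
  class(flat) <- class(cp)
  base_fit <- fit_cox(flat, covariates = c("response_state", "mskcc",
                                           "treatment"),
                      treatment_effect = "constant")
  hr_base <- base_fit$table$hr[base_fit$table$term == "response"]
  expect_lt(hr_base, hr_td)
})
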