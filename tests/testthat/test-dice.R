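std_fits_exponential <- function(rate = 0.1, n = 400, seed = 61) {
  # identical exponential fits for every arm/endpoint
  set.seed(seed)
  f <- fit_parametric(survival_sample(rexp(n, rate), rep(1L, n)),
                      "exponential")
  list(treatment = list(progression = f, discontinuation = f, death = f),
       comparator = list(progression = f, discontinuation = f, death = f))
}

test_that("simulation is deterministic given seed and config", {
  m <- default_dynamic_model()
  cfg <- simulation_config(n_patients = 300, seed = 62)
  h1 <- simulate_dynamic(m, cfg)
  h2 <- simulate_dynamic(m, cfg)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  s1 <- simulate_standard(std_fits_exponential(), cfg)
  s2 <- simulate_standard(std_fits_exponential(), cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("a degenerate dynamic model reproduces its Weibull baseline", {
  m <- unit_hr_model()
  cfg <- simulation_config(n_patients = 5000, seed = 63)
  h <- simulate_dynamic(m, cfg)
  D <- suppressWarnings(stats::ks.test(
    h$t_death, function(q) stats::pweibull(q, m$baseline_os$shape,
                                           m$baseline_os$scale))$statistic)
  expect_lt(D, 1.628 / sqrt(10000))
})

test_that("dynamic and standard engines coincide for a degenerate model", {
  # unit HRs + zero response probability vs direct draws from the same
  # baselines: distributionally indistinguishable (two-sample KS at 1%)
  m <- unit_hr_model()
  fits <- list()
  for (a in c("treatment", "comparator")) {
    fits[[a]] <- list()
    for (ep in c("progression", "discontinuation", "death")) {
      b <- switch(ep, progression = m$baseline_tp,
                  discontinuation = m$baseline_td, death = m$baseline_os)
      fits[[a]][[ep]] <- structure(
        list(family = "weibull",
             params = c(shape = b$shape, scale = b$scale)),
        class = "parametric_fit")
    }
  }
  rejections <- vapply(1:8, function(r) {
    cfg <- simulation_config(n_patients = 2000, seed = 630 + r)
    hd <- simulate_dynamic(m, cfg)
    hs <- simulate_standard(fits, cfg)
    p <- suppressWarnings(stats::ks.test(hd$t_death, hs$t_death)$p.value)
    p < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 1)
})

test_that("a strongly protective response drives the simulated death hazard", {
  # death HR 0.06 with certain instant response: the pooled simulated
  # cohort vs a no-response cohort recovers ~0.06 by Cox regression
  m <- unit_hr_model(response_prob = c(treatment = 1, comparator = 1))
  m$hr_table$death["response"] <- 0.06
  m$response_time <- lognormal_params(log(0.001), 0.01)  # instant response
  m$loss_of_response_time <- gompertz_params(-1, 1e-8)   # never lost
  m0 <- unit_hr_model(response_prob = c(treatment = 0, comparator = 0))
  cfg <- simulation_config(n_patients = 4000, seed = 64)
  h1 <- simulate_dynamic(m, cfg)
  h0 <- simulate_dynamic(m0, simulation_config(n_patients = 4000,
                                               seed = 65))
  df <- data.frame(time = c(pmin(h1$t_death, 300), pmin(h0$t_death, 300)),
                   ev = c(as.integer(h1$t_death <= 300),
                          as.integer(h0$t_death <= 300)),
                   grp = rep(1:0, each = nrow(h1)))
  fit <- survival::coxph(survival::Surv(time, ev) ~ grp, df)
  expect_equal(unname(exp(coef(fit))), 0.06, tolerance = 0.15)
})

test_that("standard engine matches closed forms and its extrapolation", {
  cfg <- simulation_config(n_patients = 5000, seed = 66)
  fits <- std_fits_exponential(rate = 0.1)
  h <- simulate_standard(fits, cfg)
  rate <- unname(fits$treatment$death$params[["rate"]])
  expect_lt(abs(mean(h$t_death) - 1 / rate), 3 * (1 / rate) / sqrt(10000))
  # no recorded summary time exceeds the horizon
  s <- summarize_histories(h, cfg)
  expect_true(all(s$rmst <= cfg$horizon))
  # medians of the simulated curves match extrapolate()'s median
  ex <- extrapolate(fits$treatment$death, horizon = 300)
  s_marg <- summarize_histories(h, cfg, cap_at_death = FALSE)
  med <- s_marg$median[s_marg$endpoint == "death" & s_marg$arm == "treatment"]
  expect_lt(abs(med - ex$median), 0.5)
  expect_error(simulate_standard(list(treatment = fits$treatment,
                                      comparator = list()), cfg),
               "missing parametric fit")
})

test_that("summaries reproduce closed forms and an independent oracle", {
  # degenerate distribution: point mass at 10 months
  h <- structure(data.frame(
    id = 1:50, arm = factor(rep(c("treatment", "comparator"), each = 25),
                            levels = c("comparator", "treatment")),
    mskcc = factor("poor"), responded = FALSE, t_response = NA_real_,
    t_loss_response = NA_real_, t_progression = 10,
    t_discontinuation = 10, t_death = 10),
    class = c("event_histories", "data.frame"), horizon = 300)
  cfg <- simulation_config(n_patients = 25, seed = 67)
  s <- summarize_histories(h, cfg)
  expect_true(all(s$median == 10))
  expect_true(all(abs(s$rmst - 10) < 1e-9))
  expect_true(all(s$s36 == 0))
  # exponential RMST vs closed form
  set.seed(68)
  n <- 20000
  he <- structure(data.frame(
    id = 1:n, arm = factor(rep(c("treatment", "comparator"), each = n / 2),
                           levels = c("comparator", "treatment")),
    mskcc = factor("poor"), responded = FALSE, t_response = NA_real_,
    t_loss_response = NA_real_, t_progression = rexp(n, 0.1),
    t_discontinuation = rexp(n, 0.1), t_death = rexp(n, 0.1)),
    class = c("event_histories", "data.frame"), horizon = 300)
  cfg2 <- simulation_config(n_patients = n / 2, seed = 69)
  se <- summarize_histories(he, cfg2, cap_at_death = FALSE)
  rm_death <- se$rmst[se$endpoint == "death"]
  expect_lt(max(abs(rm_death - 10 * (1 - exp(-30)))), 3 * 10 / sqrt(n / 2))
  # oracle re-implementation (sorting + cumulative products) on 50 patients
  set.seed(70)
  times <- rexp(50, 0.05)
  ho <- structure(data.frame(
    id = 1:50, arm = factor("treatment",
                            levels = c("comparator", "treatment")),
    mskcc = factor("poor"), responded = FALSE, t_response = NA_real_,
    t_loss_response = NA_real_, t_progression = times,
    t_discontinuation = times, t_death = times),
    class = c("event_histories", "data.frame"), horizon = 300)
  cfg3 <- simulation_config(n_patients = 25, seed = 71)
  so <- summarize_histories(ho, cfg3)
  ok <- oracle_km(pmin(times, 300), as.integer(times <= 300))
  st <- stepfun(ok$time, c(1, ok$surv))
  knots <- c(0, ok$time[ok$time < 300], 300)
  rmst_oracle <- sum(st(knots[-length(knots)]) * diff(knots))
  row <- so[so$endpoint == "death" & so$arm == "treatment", ]
  expect_equal(row$rmst, rmst_oracle, tolerance = 1e-10)
  expect_equal(row$median, min(ok$time[ok$surv <= 0.5]), tolerance = 1e-10)
  expect_equal(unname(row$s36), st(36), tolerance = 1e-12)
})

test_that("summary invariants: monotone RMST and protective-HR ordering", {
  m <- default_dynamic_model()
  cfg <- simulation_config(n_patients = 1500, seed = 72)
  h <- simulate_dynamic(m, cfg)
  s300 <- summarize_histories(h, cfg)
  cfg120 <- simulation_config(n_patients = 1500, horizon = 120, seed = 72,
                              landmark_months = c(36, 60))
  s120 <- summarize_histories(h, cfg120)
  expect_true(all(s300$rmst >= s120$rmst - 1e-9))
  expect_true(all(s300$s60 <= s300$s36 + 1e-12))
  # a protective death HR increases OS restricted mean at matched seeds
  m_hr1 <- m
  m_hr1$hr_table$death["response"] <- 1
  m_hr1$hr_table$death["post_response"] <- 1
  h_hr1 <- simulate_dynamic(m_hr1, cfg)
  a <- summarize_histories(h, cfg)
  b <- summarize_histories(h_hr1, cfg)
  os_a <- a$rmst[a$endpoint == "death" & a$arm == "treatment"]
  os_b <- b$rmst[b$endpoint == "death" & b$arm == "treatment"]
  expect_gt(os_a, os_b)
})

test_that("bootstrap standard errors behave like Monte-Carlo noise", {
  m <- default_dynamic_model()
  cfg <- simulation_config(n_patients = 400, seed = 73)
  h <- simulate_dynamic(m, cfg)
  s <- summarize_histories(h, cfg, n_boot = 25)
  expect_true(all(c("median_se", "rmst_se", "s36_se") %in% names(s)))
  expect_true(all(s$rmst_se > 0))
  expect_true(all(s$rmst_se < 20))
})
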