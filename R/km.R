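# Kaplan-Meier estimation (product-limit via survival::survfit, with
# Greenwood variance), stratified curves, and predicted-vs-observed curve
# comparison.

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator \eqn{\hat S(t) = \prod_{t_i \le t} (1 -
#' d_i/n_i)} over distinct observed times. A censoring tied with an event
#' time leaves the risk set after the event (standard convention). The
#' Greenwood variance \eqn{\hat S(t)^2 \sum d_i / \{n_i (n_i - d_i)\}} is
#' attached per step.
#'
#' @param sample A [survival_sample()].
#' @return A `km_curve` data frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `greenwood_var`, starting with a
#'   `time = 0`, `surv = 1` anchor row. The survival probability changes
#'   only at event times.
#' @examples
#' km_estimate(survival_sample(c(1, 2, 3, 4), c(0, 1, 1, 0)))
#' @export
km_estimate <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  if (!length(sample$times)) stop("empty sample")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          data = data.frame(times = sample$times,
                                            events = sample$events),
                          conf.type = "none")
  d <- sf$n.event; r <- sf$n.risk
  gw_terms <- ifelse(r > d, d / (r * (r - d)), NA_real_)
  out <- data.frame(time = c(0, sf$time),
                    n_risk = c(length(sample$times), r),
                    n_event = c(0, d), n_censor = c(0, sf$n.censor),
                    surv = c(1, sf$surv),
                    greenwood_var = c(0, sf$surv^2 * cumsum(gw_terms)))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve
#'
#' `km_surv_at()` evaluates the right-continuous step function at `t`;
#' `km_median()` returns the smallest time with \eqn{\hat S \le 0.5}
#' (`NA` if never reached); `km_rmst()` integrates the step function from
#' 0 to `horizon` (subjects censored before `horizon` contribute the last
#' step value).
#'
#' @param curve A `km_curve`.
#' @param t Times (months).
#' @param horizon Upper integration limit (months).
#' @return Numeric.
#' @export
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
}

#' @rdname km_surv_at
#' @export
km_median <- function(curve) {
  hit <- which(curve$surv <= 0.5)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

#' @rdname km_surv_at
#' @export
km_rmst <- function(curve, horizon) {
  stopifnot(horizon > 0)
  knots <- c(curve$time[curve$time < horizon], horizon)
  S <- km_surv_at(curve, knots[-length(knots)])
  sum(S * diff(knots))
}

#' Stratified Kaplan-Meier curves
#'
#' One curve per level combination of the requested stratification
#' columns. Stratifying by responder status uses the *ever-responder*
#' flag; the returned object carries an explicit immortal-time caveat in
#' its metadata, since ever-responders must have survived event-free to
#' respond.
#'
#' @param records Patient records.
#' @param endpoint `"progression"`, `"discontinuation"` or `"death"`.
#' @param strata Character vector among `"arm"`, `"mskcc"`, `"responded"`.
#' @return A named list of `km_curve` objects (empty strata omitted with
#'   a warning), with attribute `"caveat"` when responder stratification
#'   is requested.
#' @export
stratified_km <- function(records, endpoint = c("progression",
                                                "discontinuation", "death"),
                          strata = "arm") {
  endpoint <- match.arg(endpoint)
  strata <- match.arg(strata, c("arm", "mskcc", "responded"),
                      several.ok = TRUE)
  cls <- .endpoint_cols(endpoint)
  key <- interaction(records[strata], sep = "/", drop = FALSE)
  curves <- list()
  for (lev in levels(key)) {
    idx <- key == lev
    if (!any(idx)) {
      warning("empty stratum omitted: ", lev)
      next
    }
    curves[[lev]] <- km_estimate(survival_sample(records[[cls[["obs"]]]][idx],
                                                 records[[cls[["ev"]]]][idx]))
  }
  if ("responded" %in% strata)
    attr(curves, "caveat") <- paste(
      "responder strata use ever-responder status: curves are subject to",
      "immortal-time bias and are descriptive only")
  curves
}

.eval_surv <- function(x, t) {
  if (inherits(x, "km_curve")) km_surv_at(x, t)
  else if (inherits(x, "parametric_fit")) surv_function(x)(t)
  else if (is.function(x)) x(t)
  else stop("cannot evaluate survival for class ", paste(class(x), collapse = "/"))
}

.max_support <- function(x) {
  if (inherits(x, "km_curve")) max(x$time) else Inf
}

#' Compare a predicted survival curve with an observed one
#'
#' Purely descriptive discrepancy measures on a common time grid: mean
#' and maximum absolute survival-probability difference, signed area
#' between the curves (positive where the predicted curve lies above),
#' and the difference at each landmark. No hypothesis test is performed.
#'
#' @param predicted A `km_curve`, a `parametric_fit`, or a survival
#'   function of time.
#' @param observed Likewise (typically the observed `km_curve`).
#' @param grid Evaluation grid in months; default monthly from 0 to the
#'   shared support maximum.
#' @param landmarks Landmark months (only those inside the grid are
#'   reported).
#' @return A list of class `curve_comparison`: `mean_abs_diff`,
#'   `max_abs_diff`, `signed_area`, `landmark_diff`, `grid` range.
#' @export
compare_curves <- function(predicted, observed, grid = NULL,
                           landmarks = c(36, 60)) {
  if (is.null(grid)) {
    top <- min(.max_support(predicted), .max_support(observed))
    if (!is.finite(top)) stop("provide a grid for functional curves")
    grid <- seq(0, floor(top), by = 1)
  }
  if (length(grid) < 2L) stop("supports do not overlap on a usable grid")
  sp <- .eval_surv(predicted, grid)
  so <- .eval_surv(observed, grid)
  d <- sp - so
  mid <- (d[-1] + d[-length(d)]) / 2
  lm_in <- landmarks[landmarks <= max(grid)]
  lm_diff <- if (length(lm_in)) {
    stats::setNames(.eval_surv(predicted, lm_in) - .eval_surv(observed, lm_in),
                    paste0("s", lm_in))
  } else stats::setNames(numeric(0), character(0))
  structure(list(
    mean_abs_diff = mean(abs(d)), max_abs_diff = max(abs(d)),
    signed_area = sum(mid * diff(grid)),
    landmark_diff = lm_diff,
    grid = range(grid)), class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(paste0("Curve comparison on [%g, %g] months: mean |dS| = ",
                     "%.4f, max |dS| = %.4f, signed area = %.2f\n"),
              x$grid[1], x$grid[2], x$mean_abs_diff, x$max_abs_diff,
              x$signed_area))
  if (length(x$landmark_diff))
    cat("  landmark differences:",
        paste(sprintf("%s = %+.4f", names(x$landmark_diff),
                      x$landmark_diff), collapse = ", "), "\n")
  invisible(x)
}
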