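# Package-wide Weibull convention: S(t) = exp(-(t/scale)^shape), so the
# hazard is h(t) = (shape/scale) * (t/scale)^(shape - 1), time in months.

#' Weibull baseline parameters
#'
#' Container for a Weibull baseline hazard in the package-wide
#' parameterization \eqn{S(t) = \exp\{-(t/\lambda)^\gamma\}} with
#' `shape` \eqn{= \gamma > 0} and `scale` \eqn{= \lambda > 0} in months.
#'
#' @param shape Positive shape parameter.
#' @param scale Positive scale parameter (months).
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(1.2, 10)
#' @export
weibull_params <- function(shape, scale) {
  stopifnot(is.numeric(shape), length(shape) == 1L,
            is.numeric(scale), length(scale) == 1L)
  if (!is.finite(shape) || shape <= 0) stop("`shape` must be finite and > 0")
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be finite and > 0")
  structure(list(shape = as.numeric(shape), scale = as.numeric(scale)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(shape = %.4g, scale = %.4g months); median %.3g months\n",
              x$shape, x$scale, x$scale * log(2)^(1 / x$shape)))
  invisible(x)
}

#' Log-normal time-to-event parameters (of log-time, months)
#'
#' @param meanlog Mean of log event time.
#' @param sdlog Standard deviation of log event time, > 0.
#' @return An object of class `lognormal_params`.
#' @export
lognormal_params <- function(meanlog, sdlog) {
  stopifnot(is.numeric(meanlog), length(meanlog) == 1L, is.finite(meanlog),
            is.numeric(sdlog), length(sdlog) == 1L)
  if (!is.finite(sdlog) || sdlog <= 0) stop("`sdlog` must be finite and > 0")
  structure(list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog)),
            class = "lognormal_params")
}

#' Gompertz time-to-event parameters
#'
#' Hazard \eqn{h(t) = b e^{a t}} with `shape` \eqn{= a \in R} and
#' `rate` \eqn{= b > 0}. A negative shape gives an improper distribution:
#' a fraction \eqn{\exp(b/a)} of subjects never experience the event
#' (see [gompertz_cure_fraction()]).
#'
#' @param shape Real shape parameter `a` (per month).
#' @param rate Positive rate parameter `b` (per month).
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(shape, rate) {
  stopifnot(is.numeric(shape), length(shape) == 1L,
            is.numeric(rate), length(rate) == 1L)
  if (!is.finite(shape)) stop("`shape` must be finite")
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be finite and > 0")
  structure(list(shape = as.numeric(shape), rate = as.numeric(rate)),
            class = "gompertz_params")
}

#' Never-event fraction of an improper Gompertz distribution
#'
#' For `shape` \eqn{a < 0} the Gompertz cumulative hazard plateaus at
#' \eqn{b/|a|}, so \eqn{S(\infty) = \exp(b/a) > 0}: the long-term fraction
#' that never experiences the event (e.g. durable responders who never
#' lose response).
#'
#' @param params A [gompertz_params()] object.
#' @return The limiting survival fraction (0 for `shape >= 0`).
#' @export
gompertz_cure_fraction <- function(params) {
  stopifnot(inherits(params, "gompertz_params"))
  if (params$shape >= 0) 0 else exp(params$rate / params$shape)
}

#' Weibull cumulative hazard and its inverse
#'
#' `weibull_cumhaz()` evaluates \eqn{H_0(t) = (t/\lambda)^\gamma};
#' `weibull_cumhaz_inv()` solves \eqn{H_0(t) = H} for `t`.
#'
#' @param t Times (months), non-negative.
#' @param H Cumulative hazard values, non-negative.
#' @param baseline A [weibull_params()] object.
#' @return Numeric vector.
#' @export
weibull_cumhaz <- function(t, baseline) {
  stopifnot(inherits(baseline, "weibull_params"))
  (t / baseline$scale)^baseline$shape
}

#' @rdname weibull_cumhaz
#' @export
weibull_cumhaz_inv <- function(H, baseline) {
  stopifnot(inherits(baseline, "weibull_params"))
  baseline$scale * H^(1 / baseline$shape)
}

# Fast internal kernel: find t with integrated hazard equal to `target`,
# where the hazard is a Weibull baseline times a piecewise-constant
# multiplier (starts[1] == 0, strictly increasing; last piece open-ended).
# Returns Inf when the total cumulative hazard never reaches `target`.
.piecewise_invert <- function(target, shape, scale, starts, mults) {
  h0 <- (starts / scale)^shape
  k <- length(starts)
  acc <- 0
  for (i in seq_len(k)) {
    hi <- if (i < k) h0[i + 1L] else Inf
    m <- mults[i]
    dh <- if (m == 0) 0 else m * (hi - h0[i])
    if (target <= acc + dh) {
      return(scale * (h0[i] + (target - acc) / m)^(1 / shape))
    }
    acc <- acc + dh
  }
  Inf
}

#' Sample an event time under a piecewise-multiplied Weibull hazard
#'
#' Draws the event time whose hazard is a Weibull baseline multiplied by a
#' piecewise-constant schedule of hazard ratios, by inverting the integrated
#' hazard at \eqn{-\log(u)}: the returned `t` solves
#' \eqn{H(t) = \sum_i m_i [H_0(\min(t, s_{i+1})) - H_0(s_i)] = -\log u}.
#' This is how the microsimulation engine realizes endpoint times whose
#' hazard changes at response achievement, loss of response, and the
#' treatment-effect inflection point. If the total cumulative hazard over
#' \eqn{[0, \infty)} is below \eqn{-\log u} (all-zero multipliers, or a
#' decreasing tail), `Inf` is returned: the event never happens.
#'
#' @param baseline A [weibull_params()] baseline.
#' @param schedule A data frame with columns `start` (months; first must be
#'   0, strictly increasing) and `multiplier` (finite, >= 0). Each row's
#'   multiplier applies from its `start` to the next row's `start`.
#' @param u Uniform(0, 1) draw(s); vectorized.
#' @return Event time(s) in months, possibly `Inf`.
#' @examples
#' # shape 1 reduces to an exponential: scale 10, u = 0.5 gives 10 log 2
#' sample_event_time_piecewise(
#'   weibull_params(1, 10),
#'   data.frame(start = 0, multiplier = 1), u = 0.5)
#' @export
sample_event_time_piecewise <- function(baseline, schedule, u) {
  stopifnot(inherits(baseline, "weibull_params"), is.data.frame(schedule),
            all(c("start", "multiplier") %in% names(schedule)))
  starts <- as.numeric(schedule$start)
  mults <- as.numeric(schedule$multiplier)
  if (length(starts) < 1L || starts[1] != 0)
    stop("schedule must start at time 0")
  if (any(diff(starts) <= 0)) stop("schedule start times must be strictly increasing")
  if (any(!is.finite(mults)) || any(mults < 0))
    stop("schedule multipliers must be finite and >= 0")
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("`u` must lie strictly inside (0, 1)")
  vapply(u, function(ui) {
    .piecewise_invert(-log(ui), baseline$shape, baseline$scale, starts, mults)
  }, numeric(1))
}
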