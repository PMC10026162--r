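#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function, computed with
#' [survival::survfit()]. With fully observed data (no censoring) it equals
#' one minus the empirical distribution function. Ties between events and
#' censorings at the same time are handled in the standard way: events are
#' processed before censorings.
#'
#' @param data A [surv_data()] object.
#' @return An object of class `"km_curve"` with components `event_times`,
#'   `survival`, `at_risk` and `n_events` (restricted to times with at least
#'   one event), plus the full right-continuous step function in
#'   `step_times` / `step_survival` for evaluation between jumps.
#' @seealso [km_survival()]
#' @export
km_estimate <- function(data) {
  stopifnot(is_surv_data(data))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(data))
  ev <- sf$n.event > 0
  structure(
    list(event_times = sf$time[ev],
         survival = sf$surv[ev],
         at_risk = as.integer(sf$n.risk[ev]),
         n_events = as.integer(sf$n.event[ev]),
         step_times = sf$time,
         step_survival = sf$surv,
         n = nrow(data)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times, S(max) = %.3f\n",
              x$n, length(x$event_times),
              if (length(x$step_survival)) min(x$step_survival) else 1))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation: between jumps the value of the most
#' recent jump is carried forward; before the first recorded time the
#' estimate is 1.
#'
#' @param km A `"km_curve"` from [km_estimate()].
#' @param t Numeric vector of non-negative times.
#' @return Survival probabilities at `t`.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_curve"), is.numeric(t), all(t >= 0))
  if (!length(km$step_times)) return(rep(1, length(t)))
  stats::approx(x = c(0, km$step_times), y = c(1, km$step_survival),
                xout = t, method = "constant", f = 0, rule = 2)$y
}
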