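#' Blending weight specification
#'
#' Defines the time-varying weight \eqn{\pi(t)} that controls how the
#' observed-data survival curve and the external survival curve are mixed.
#' The weight is the cumulative distribution function of a
#' \eqn{Beta(\alpha, \beta)} random variable evaluated at the rescaled time
#' \eqn{(t - a)/(b - a)}, so it is exactly 0 before the blending interval
#' \eqn{[a, b]} and exactly 1 after it. With `alpha = beta = 1` the weight is
#' a linear ramp across the interval.
#'
#' The degenerate choice `blend_start == blend_end == horizon` disables
#' blending altogether: the weight is 0 everywhere (and its density is 0
#' everywhere), so the blended curve reduces to the observed-data curve over
#' the whole time frame.
#'
#' @param alpha,beta Positive shape parameters of the Beta distribution.
#'   `alpha < beta` front-loads the blending (steeper early rise);
#'   `alpha > beta` back-loads it.
#' @param blend_start,blend_end Start `a` and end `b` of the blending
#'   interval, in months. Must satisfy `0 <= a < b <= horizon`, except the
#'   degenerate case `a == b == horizon`.
#' @param horizon Upper end `T*` of the evaluation horizon, in months.
#'
#' @return An object of class `"weight_spec"`.
#' @seealso [blend_weight()], [blend_weight_density()], [blend_survival()]
#' @examples
#' ws <- weight_spec(alpha = 2, beta = 5, blend_start = 3, blend_end = 13,
#'                   horizon = 20)
#' blend_weight(c(3, 8, 13), ws)
#' @export
weight_spec <- function(alpha = 1, beta = 1, blend_start, blend_end,
                        horizon) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(blend_start), length(blend_start) == 1L,
            is.numeric(blend_end), length(blend_end) == 1L,
            is.numeric(horizon), length(horizon) == 1L,
            is.finite(blend_start), is.finite(blend_end), is.finite(horizon))
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must both be positive")
  degenerate <- (blend_start == blend_end) && (blend_end == horizon)
  if (!degenerate) {
    if (!(blend_start >= 0 && blend_start < blend_end &&
          blend_end <= horizon))
      stop("need 0 <= blend_start < blend_end <= horizon ",
           "(or blend_start == blend_end == horizon to disable blending)")
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         blend_start = as.numeric(blend_start),
         blend_end = as.numeric(blend_end),
         horizon = as.numeric(horizon), degenerate = degenerate),
    class = "weight_spec")
}

is_weight_spec <- function(x) inherits(x, "weight_spec")

#' @export
print.weight_spec <- function(x, ...) {
  if (x$degenerate) {
    cat("Blending weight: disabled (a = b = T* =", x$horizon, "months)\n")
  } else {
    cat(sprintf(
      "Blending weight: Beta(%g, %g) CDF over [%g, %g] months (horizon %g)\n",
      x$alpha, x$beta, x$blend_start, x$blend_end, x$horizon))
  }
  invisible(x)
}

check_weight_times <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("times must be finite numeric values")
  if (any(t < 0)) stop("times must be non-negative")
  as.numeric(t)
}

#' Evaluate the blending weight
#'
#' Computes \eqn{\pi(t) = F_{Beta}((t-a)/(b-a); \alpha, \beta)}. The rescaled
#' argument is clipped to \eqn{[0, 1]} before evaluation, so times at (or a
#' floating-point hair outside) the interval boundaries return exactly 0
#' or 1.
#'
#' @param t Numeric vector of non-negative times (months).
#' @param spec A [weight_spec()].
#' @return Numeric vector of weights in \eqn{[0, 1]}, non-decreasing in `t`.
#' @export
blend_weight <- function(t, spec) {
  stopifnot(is_weight_spec(spec))
  t <- check_weight_times(t)
  if (spec$degenerate) return(rep(0, length(t)))
  x <- (t - spec$blend_start) / (spec$blend_end - spec$blend_start)
  x <- pmin(pmax(x, 0), 1)
  stats::pbeta(x, spec$alpha, spec$beta)
}

#' Evaluate the blending weight density
#'
#' The time derivative of [blend_weight()]:
#' \eqn{f_{Beta}((t-a)/(b-a))/(b-a)} inside the blending interval and exactly
#' 0 outside it. It integrates to 1 over \eqn{[a, b]} and enters the blended
#' hazard as the factor multiplying the cumulative-hazard difference.
#'
#' @inheritParams blend_weight
#' @return Numeric vector of non-negative rates (per month).
#' @export
blend_weight_density <- function(t, spec) {
  stopifnot(is_weight_spec(spec))
  t <- check_weight_times(t)
  if (spec$degenerate) return(rep(0, length(t)))
  w <- spec$blend_end - spec$blend_start
  x <- (t - spec$blend_start) / w
  out <- numeric(length(t))
  inside <- x >= 0 & x <= 1
  out[inside] <- stats::dbeta(x[inside], spec$alpha, spec$beta) / w
  # Beta densities with alpha < 1 or beta < 1 are infinite at the edges;
  # the blended-hazard formula only ever uses interior points, but keep the
  # value finite at exact boundaries for alpha, beta >= 1 and propagate Inf
  # honestly otherwise.
  out
}
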