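#' Fit a blended survival model
#'
#' The main entry point: fits the Bayesian piecewise-exponential model to
#' the trial follow-up, builds an external parametric curve (from expert
#' elicitation or hard external data), and blends the two survival
#' ensembles through a Beta-CDF weight over the blending interval,
#' producing survival and hazard estimates with credible intervals over the
#' whole horizon.
#'
#' The observed component is fitted on `n_intervals` equal-width intervals
#' over `[0, follow_up_end]` and extrapolated to the horizon by
#' forward-simulating the fitted random walk; the external component is a
#' maximum-likelihood parametric fit with asymptotic-normal parameter
#' draws. Both ensembles are resampled to a common draw count and paired
#' independently by index.
#'
#' @param data A [surv_data()] object (the trial IPD), or anything
#'   accepted by [surv_data()] coercion via a data frame with `time` and
#'   `event` columns.
#' @param external The external evidence: an [elicitation_spec()] (expert
#'   constraints, translated into pseudo-data), a [surv_data()] (hard
#'   external IPD), or a ready-made `"parametric_fit"`.
#' @param weight A [weight_spec()] giving the blending interval, Beta
#'   shapes and horizon.
#' @param family Parametric family for the external fit (ignored when
#'   `external` is already a fit).
#' @param n_intervals Number of piecewise-hazard intervals over follow-up.
#' @param follow_up_end End of trial follow-up (months); defaults to the
#'   largest observed time.
#' @param rw_order Random-walk prior order (1 or 2).
#' @param n_draws Posterior draws for each component and the blend.
#' @param grid Evaluation grid; defaults to monthly steps from 0 to the
#'   weight horizon.
#' @param seed Integer seed controlling every stochastic step.
#' @param level Credible level for summaries.
#' @return An object of class `"blendsurv"` with components `observed_fit`,
#'   `external_fit`, `weight`, `km`, `grid` and `curves` (a list of
#'   [curve_draws()]: `obs`, `ext`, `blended` survival and `obs_hazard`,
#'   `ext_hazard`, `blended_hazard`).
#' @examples
#' \donttest{
#' sc <- trial_scenario(200, "weibull", list(shape = 1.3, scale = 90),
#'                      admin_censor_time = 48, seed = 7)
#' ipd <- simulate_trial(sc)
#' elic <- elicitation_spec(data.frame(time = 120, survival = 0.15),
#'                          n_effective = 100, t_max = 240)
#' ws <- weight_spec(alpha = 1, beta = 1, blend_start = 48,
#'                   blend_end = 150, horizon = 180)
#' fit <- blendsurv(ipd, elic, ws, n_draws = 500, seed = 7)
#' summary(fit, times = c(48, 96, 180))
#' }
#' @export
blendsurv <- function(data, external, weight, family = "gompertz",
                      n_intervals = 8, follow_up_end = NULL, rw_order = 1,
                      n_draws = 2000, grid = NULL, seed = 1,
                      level = 0.95) {
  if (!is_surv_data(data)) data <- validate_surv_data(as.data.frame(data))
  stopifnot(is_weight_spec(weight))
  seed <- as.integer(seed)
  if (is.null(grid)) grid <- seq(0, weight$horizon, by = 1)
  if (max(grid) > weight$horizon)
    stop("grid extends beyond the weight horizon")

  # observed component
  cuts <- make_cutpoints(data, n_intervals, follow_up_end)
  pw <- fit_piecewise(data, cuts, rw_order = rw_order, n_draws = n_draws,
                      seed = seed)
  if (weight$horizon > max(cuts))
    pw <- extend_posterior(pw, horizon = weight$horizon, seed = seed + 10L)

  # external component
  ext_fit <- external_to_fit(external, family, n_draws, seed)

  obs_s <- survival_draws(pw, grid)
  obs_h <- hazard_draws(pw, grid)
  obs_H <- cumhaz_draws(pw, grid)
  ext_s <- parametric_survival(ext_fit, grid)
  ext_h <- parametric_hazard(ext_fit, grid)
  ext_H <- parametric_cumhaz(ext_fit, grid)

  al <- align_draws(obs_s, ext_s, n = n_draws, seed = seed + 20L)
  al_h <- align_draws(obs_h, ext_h, n = n_draws, seed = seed + 20L)
  al_H <- align_draws(obs_H, ext_H, n = n_draws, seed = seed + 20L)
  obs_s <- al$a; ext_s <- al$b
  obs_h <- al_h$a; ext_h <- al_h$b

  ble_s <- blend_survival(obs_s, ext_s, weight)
  ble_h <- blend_hazard(obs_h, ext_h, al_H$a, al_H$b, weight)

  structure(
    list(call = match.call(),
         data = data,
         km = km_estimate(data),
         observed_fit = pw,
         external_fit = ext_fit,
         weight = weight,
         grid = grid,
         level = level,
         seed = seed,
         curves = list(obs = obs_s, ext = ext_s, blended = ble_s,
                       obs_hazard = obs_h, ext_hazard = ext_h,
                       blended_hazard = ble_h)),
    class = "blendsurv")
}

external_to_fit <- function(external, family, n_draws, seed) {
  if (is_parametric_fit(external)) return(external)
  if (is_elicitation_spec(external)) {
    pseudo <- build_pseudo_data(external, seed = seed + 30L)
    return(fit_parametric(pseudo, family = family, n_draws = n_draws,
                          seed = seed + 40L))
  }
  if (is_surv_data(external) || is.data.frame(external)) {
    if (!is_surv_data(external))
      external <- validate_surv_data(as.data.frame(external))
    return(fit_parametric(external, family = family, n_draws = n_draws,
                          seed = seed + 40L))
  }
  stop("'external' must be an elicitation_spec, surv_data or parametric_fit")
}

#' @export
print.blendsurv <- function(x, ...) {
  cat("Blended survival model\n")
  cat(sprintf("  Trial data: %d subjects, %d events (%.1f%% censored)\n",
              nrow(x$data), sum(x$data$event),
              100 * mean(x$data$event == 0)))
  cat(sprintf("  Observed component: piecewise exponential, %d intervals, RW%d prior\n",
              x$observed_fit$n_fitted, x$observed_fit$rw_order))
  cat(sprintf("  External component: %s fit (%d subjects)\n",
              x$external_fit$family, x$external_fit$n))
  if (x$weight$degenerate) {
    cat("  Blending: disabled (blended curve = observed curve)\n")
  } else {
    cat(sprintf("  Blending: Beta(%g, %g) weight over [%g, %g] months, horizon %g\n",
                x$weight$alpha, x$weight$beta, x$weight$blend_start,
                x$weight$blend_end, x$weight$horizon))
  }
  invisible(x)
}

#' @describeIn blendsurv Survival summaries at selected times for all three
#'   curves.
#' @param object,x A `"blendsurv"` object.
#' @param times Times at which to summarize (defaults to yearly steps).
#' @param ... Unused.
#' @export
summary.blendsurv <- function(object, times = NULL, level = NULL, ...) {
  if (is.null(level)) level <- object$level
  if (is.null(times))
    times <- object$grid[object$grid %% 12 == 0 | object$grid == max(object$grid)]
  times <- sort(unique(times))
  if (!all(times %in% object$grid))
    stop("requested times must lie on the fitted grid")
  pick <- match(times, object$grid)
  one <- function(curve, label) {
    s <- summary(curve, level = level)[pick, , drop = FALSE]
    s$curve <- label
    s
  }
  out <- rbind(one(object$curves$blended, "blended"),
               one(object$curves$obs, "observed"),
               one(object$curves$ext, "external"))
  rownames(out) <- NULL
  structure(list(table = out[, c("curve", "time", "mean", "lower",
                                 "upper")],
                 level = level),
            class = "summary.blendsurv")
}

#' @export
print.summary.blendsurv <- function(x, digits = 4, ...) {
  cat(sprintf("Survival summaries (mean and %g%% credible interval)\n",
              100 * x$level))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @describeIn blendsurv Pointwise survival or hazard estimates at new
#'   times (must lie within the fitted horizon).
#' @param newtimes Times at which to predict; defaults to the fitted grid.
#' @param type `"survival"` or `"hazard"`.
#' @param summarize If `TRUE` (default) return a `time, mean, lower, upper`
#'   table; otherwise the full draw matrix.
#' @export
predict.blendsurv <- function(object, newtimes = NULL,
                              type = c("survival", "hazard"),
                              summarize = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newtimes)) newtimes <- object$grid
  newtimes <- sort(unique(as.numeric(newtimes)))
  if (any(newtimes < 0) || any(newtimes > object$weight$horizon))
    stop("newtimes must lie in [0, horizon]")
  obs_s <- survival_draws(object$observed_fit, newtimes)
  ext_s <- parametric_survival(object$external_fit, newtimes)
  n <- nrow(object$curves$blended$draws)
  al <- align_draws(obs_s, ext_s, n = n, seed = object$seed + 20L)
  if (type == "survival") {
    out <- blend_survival(al$a, al$b, object$weight)
  } else {
    obs_h <- hazard_draws(object$observed_fit, newtimes)
    ext_h <- parametric_hazard(object$external_fit, newtimes)
    al_h <- align_draws(obs_h, ext_h, n = n, seed = object$seed + 20L)
    obs_H <- cumhaz_draws(object$observed_fit, newtimes)
    ext_H <- parametric_cumhaz(object$external_fit, newtimes)
    al_H <- align_draws(obs_H, ext_H, n = n, seed = object$seed + 20L)
    out <- blend_hazard(al_h$a, al_h$b, al_H$a, al_H$b, object$weight)
  }
  if (summarize) summary(out, level = object$level) else out
}

#' @describeIn blendsurv Plot the blended curve with credible band, the
#'   observed and external component means, and the Kaplan-Meier overlay.
#' @param what `"survival"` or `"hazard"` panel.
#' @export
plot.blendsurv <- function(x, what = c("survival", "hazard"), level = NULL,
                           ...) {
  what <- match.arg(what)
  if (is.null(level)) level <- x$level
  if (what == "survival") {
    plot(x$curves$blended, level = level, col = "firebrick",
         ylab = "Survival", ...)
    so <- summary(x$curves$obs, level = level)
    se <- summary(x$curves$ext, level = level)
    graphics::lines(so$time, so$mean, col = "forestgreen", lty = 2)
    graphics::lines(se$time, se$mean, col = "steelblue", lty = 3)
    graphics::lines(stats::stepfun(x$km$step_times,
                                   c(1, x$km$step_survival)),
                    do.points = FALSE, col = "grey40")
    graphics::legend("topright", bty = "n",
                     legend = c("blended", "observed", "external", "KM"),
                     col = c("firebrick", "forestgreen", "steelblue",
                             "grey40"),
                     lty = c(1, 2, 3, 1), lwd = c(2, 1, 1, 1))
  } else {
    plot(x$curves$blended_hazard, level = level, col = "firebrick",
         ylab = "Hazard (per month)", ...)
    so <- summary(x$curves$obs_hazard, level = level)
    se <- summary(x$curves$ext_hazard, level = level)
    graphics::lines(so$time, so$mean, col = "forestgreen", lty = 2)
    graphics::lines(se$time, se$mean, col = "steelblue", lty = 3)
    graphics::legend("topright", bty = "n",
                     legend = c("blended", "observed", "external"),
                     col = c("firebrick", "forestgreen", "steelblue"),
                     lty = c(1, 2, 3), lwd = c(2, 1, 1))
  }
  invisible(x)
}
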