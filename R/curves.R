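#' Ensemble of curves on a common time grid
#'
#' The exchange container between the observed-data fit, the external fit
#' and the blending step: a draws-by-times matrix of survival, hazard or
#' cumulative-hazard values on a strictly increasing grid. Survival
#' ensembles are validated to lie in `[0, 1]`, be non-increasing along the
#' grid in every draw, and equal 1 at `t = 0` when the grid includes 0.
#'
#' Blended ensembles are the one exception to per-draw monotonicity: when a
#' draw of the observed component crosses its paired external draw inside
#' the blending interval, the blended draw can rise locally even though the
#' mean curve behaves. [blend_survival()] therefore constructs its result
#' with `check_monotone = FALSE`.
#'
#' @param grid Strictly increasing numeric time vector (months).
#' @param draws Numeric matrix, one row per draw, one column per grid time.
#' @param kind One of `"survival"`, `"hazard"`, `"cumulative_hazard"`.
#' @param check_monotone Enforce per-draw monotonicity for survival curves
#'   and non-negativity for hazard curves. Blended outputs relax both: a
#'   blended hazard draw is the exact derivative of its (possibly locally
#'   rising) blended survival draw and may dip below zero.
#' @return An object of class `"curve_draws"`.
#' @export
curve_draws <- function(grid, draws,
                        kind = c("survival", "hazard",
                                 "cumulative_hazard"),
                        check_monotone = TRUE) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid)
  draws <- as.matrix(draws)
  dimnames(draws) <- NULL
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (ncol(draws) != length(grid))
    stop("draws must have one column per grid time")
  if (anyNA(draws)) stop("draws contain missing values")
  tol <- 1e-8
  if (kind == "survival") {
    if (any(draws < -tol) || any(draws > 1 + tol))
      stop("survival values must lie in [0, 1]")
    draws <- pmin(pmax(draws, 0), 1)
    if (check_monotone && ncol(draws) > 1 &&
        any(draws[, -1, drop = FALSE] - draws[, -ncol(draws), drop = FALSE] >
            tol))
      stop("survival draws must be non-increasing along the grid")
    if (grid[1] == 0 && any(abs(draws[, 1] - 1) > tol))
      stop("survival at t = 0 must be 1")
  } else if (check_monotone) {
    if (any(draws < -tol)) stop(kind, " values must be non-negative")
    draws <- pmax(draws, 0)
  }
  structure(list(grid = grid, draws = draws, kind = kind),
            class = "curve_draws")
}

is_curve_draws <- function(x) inherits(x, "curve_draws")

#' @export
print.curve_draws <- function(x, ...) {
  cat(sprintf("curve_draws [%s]: %d draws on %d grid times in [%g, %g]\n",
              x$kind, nrow(x$draws), length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

check_common <- function(..., what = "inputs") {
  curves <- list(...)
  g <- curves[[1]]$grid
  n <- nrow(curves[[1]]$draws)
  for (cc in curves[-1]) {
    if (length(cc$grid) != length(g) || any(cc$grid != g))
      stop(what, " must share the same time grid")
    if (nrow(cc$draws) != n)
      stop(what, " must have the same number of draws; ",
           "use align_draws() to resample to a common count")
  }
  invisible(TRUE)
}

#' Blend two survival ensembles
#'
#' The blended survival curve is the weight-geometric combination
#' \deqn{S_{ble}(t) = S_{obs}(t)^{1-\pi(t)} \times S_{ext}(t)^{\pi(t)},}
#' applied draw by draw (draws are paired by index). Where the weight is 0
#' the result equals the observed curve exactly, and where it is 1 the
#' external curve; `0^0` is 1, so a component that has already reached zero
#' contributes nothing when its weight vanishes.
#'
#' @param obs,ext Survival [curve_draws()] on a common grid with equal draw
#'   counts.
#' @param spec A [weight_spec()].
#' @return A survival [curve_draws()].
#' @export
blend_survival <- function(obs, ext, spec) {
  stopifnot(is_curve_draws(obs), is_curve_draws(ext), is_weight_spec(spec),
            obs$kind == "survival", ext$kind == "survival")
  check_common(obs, ext, what = "observed and external ensembles")
  pi_t <- blend_weight(obs$grid, spec)
  # row-wise: S_obs^(1-pi) * S_ext^pi ; R defines 0^0 = 1
  ble <- sweep(obs$draws, 2, 1 - pi_t, `^`) *
    sweep(ext$draws, 2, pi_t, `^`)
  curve_draws(obs$grid, ble, kind = "survival", check_monotone = FALSE)
}

#' Blend two hazard ensembles
#'
#' Closed-form hazard of the blended survival curve:
#' \deqn{h_{ble}(t) = (1-\pi(t)) h_{obs}(t) + \pi(t) h_{ext}(t)
#'   + \frac{f_{Beta}\left(\frac{t-a}{b-a}\right)}{b-a}
#'     \left(H_{ext}(t) - H_{obs}(t)\right),}
#' where the last term — the weight density times the cumulative-hazard
#' difference — is what allows turning points inside the blending interval.
#' Outside `[a, b]` the blended hazard equals the observed (before `a`) or
#' external (after `b`) hazard exactly.
#'
#' @param obs_h,ext_h Hazard [curve_draws()].
#' @param obs_H,ext_H Cumulative-hazard [curve_draws()].
#' @param spec A [weight_spec()].
#' @return A hazard [curve_draws()].
#' @export
blend_hazard <- function(obs_h, ext_h, obs_H, ext_H, spec) {
  stopifnot(is_curve_draws(obs_h), is_curve_draws(ext_h),
            is_curve_draws(obs_H), is_curve_draws(ext_H),
            is_weight_spec(spec),
            obs_h$kind == "hazard", ext_h$kind == "hazard",
            obs_H$kind == "cumulative_hazard",
            ext_H$kind == "cumulative_hazard")
  check_common(obs_h, ext_h, obs_H, ext_H, what = "hazard inputs")
  g <- obs_h$grid
  pi_t <- blend_weight(g, spec)
  f_t <- blend_weight_density(g, spec)
  # a zero weight annihilates its term even against an infinite hazard
  # (the 0 * Inf analogue of the 0^0 = 1 convention in blend_survival)
  wprod <- function(m, w) {
    out <- sweep(m, 2, w, `*`)
    out[, w == 0] <- 0
    out
  }
  h <- wprod(obs_h$draws, 1 - pi_t) + wprod(ext_h$draws, pi_t) +
    wprod(ext_H$draws - obs_H$draws, f_t)
  curve_draws(g, h, kind = "hazard", check_monotone = FALSE)
}

#' Cumulative hazard from a survival ensemble
#'
#' \eqn{H(t) = -\log S(t)} per draw.
#'
#' @param curve A survival [curve_draws()].
#' @return A cumulative-hazard [curve_draws()].
#' @export
cumulative_hazard <- function(curve) {
  stopifnot(is_curve_draws(curve), curve$kind == "survival")
  curve_draws(curve$grid, -log(curve$draws), kind = "cumulative_hazard")
}

#' Pointwise summary of a curve ensemble
#'
#' Mean and equal-tailed interval across draws at every grid time.
#'
#' @param object A [curve_draws()] with at least two draws.
#' @param level Interval level in `[0, 1)`; `level = 0` collapses both
#'   bounds onto the median.
#' @param ... Unused.
#' @return A data frame with columns `time`, `mean`, `lower`, `upper`.
#' @export
summary.curve_draws <- function(object, level = 0.95, ...) {
  if (nrow(object$draws) < 2)
    stop("need at least 2 draws to summarize")
  stopifnot(level >= 0, level < 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(object$draws, 2, stats::quantile, probs = probs,
              names = FALSE)
  data.frame(time = object$grid,
             mean = colMeans(object$draws),
             lower = qs[1, ],
             upper = qs[2, ])
}

#' Resample two ensembles to a common draw count
#'
#' Bootstrap (with replacement) each ensemble independently to `n` draws so
#' they can be paired by index for blending; an ensemble already holding
#' exactly `n` draws is returned unchanged.
#'
#' @param a,b [curve_draws()] objects on any grids.
#' @param n Target draw count.
#' @param seed Integer seed.
#' @return A list with elements `a` and `b`.
#' @export
align_draws <- function(a, b, n, seed = 1) {
  stopifnot(is_curve_draws(a), is_curve_draws(b), n >= 1)
  set.seed(as.integer(seed))
  resample <- function(cc) {
    if (nrow(cc$draws) == n) return(cc)
    idx <- sample.int(nrow(cc$draws), n, replace = TRUE)
    curve_draws(cc$grid, cc$draws[idx, , drop = FALSE], kind = cc$kind)
  }
  list(a = resample(a), b = resample(b))
}

#' @export
plot.curve_draws <- function(x, level = 0.95, add = FALSE, col = "black",
                             band_col = grDevices::adjustcolor(col, 0.2),
                             xlab = "Time (months)", ylab = x$kind,
                             ...) {
  s <- summary(x, level = level)
  if (!add) {
    ylim <- if (x$kind == "survival") c(0, 1) else range(s$lower, s$upper)
    graphics::plot(s$time, s$mean, type = "n", xlab = xlab, ylab = ylab,
                   ylim = ylim, ...)
  }
  graphics::polygon(c(s$time, rev(s$time)), c(s$lower, rev(s$upper)),
                    col = band_col, border = NA)
  graphics::lines(s$time, s$mean, col = col, lwd = 2)
  invisible(x)
}
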