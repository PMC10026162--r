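#' Equally spaced interval cut points over the follow-up period
#'
#' @param data A [surv_data()] object.
#' @param n_intervals Number of hazard intervals `K` (>= 1).
#' @param follow_up_end End of follow-up in months; must be at least the
#'   largest observed time. Defaults to the largest observed time.
#' @return Numeric vector of `n_intervals + 1` cut points from 0 to
#'   `follow_up_end`.
#' @export
make_cutpoints <- function(data, n_intervals, follow_up_end = NULL) {
  stopifnot(is_surv_data(data), n_intervals >= 1)
  tmax <- max(data$time)
  if (is.null(follow_up_end)) follow_up_end <- tmax
  if (follow_up_end < tmax)
    stop("follow_up_end (", follow_up_end, ") is below the largest observed ",
         "time (", tmax, "); truncate the data or supply a larger value")
  seq(0, follow_up_end, length.out = n_intervals + 1)
}

#' Per-interval event and exposure counts
#'
#' Sufficient statistics for the piecewise-exponential likelihood. Intervals
#' are left-open right-closed `(u[k-1], u[k]]`: an event exactly at a cut
#' point belongs to the interval it closes. Exposure is the person-time each
#' subject accrues in each interval, so total exposure equals the sum of all
#' observed times.
#'
#' @param data A [surv_data()] object.
#' @param cutpoints Strictly increasing cut points starting at 0 and
#'   spanning all observed times.
#' @return A data frame with columns `start`, `end`, `events`, `exposure`.
#' @export
interval_counts <- function(data, cutpoints) {
  stopifnot(is_surv_data(data))
  cutpoints <- as.numeric(cutpoints)
  if (is.unsorted(cutpoints, strictly = TRUE) || cutpoints[1] != 0)
    stop("cutpoints must be strictly increasing and start at 0")
  K <- length(cutpoints) - 1L
  if (any(data$time > cutpoints[K + 1L]))
    stop("observed times beyond the last cutpoint (",
         cutpoints[K + 1L], ")")
  lo <- cutpoints[-(K + 1L)]
  hi <- cutpoints[-1L]
  # exposure: overlap of [0, t_i] with each interval
  exposure <- vapply(seq_len(K), function(k) {
    sum(pmax(0, pmin(data$time, hi[k]) - lo[k]))
  }, numeric(1))
  # events: interval (u[k-1], u[k]] containing t_i
  idx <- findInterval(data$time, cutpoints, left.open = TRUE)
  idx[data$time == 0] <- 1L  # unreachable (times > 0), defensive
  events <- vapply(seq_len(K), function(k) {
    sum(data$event[idx == k])
  }, numeric(1))
  data.frame(start = lo, end = hi, events = events, exposure = exposure)
}

#' Piecewise-exponential log-likelihood from interval counts
#'
#' \eqn{\ell(\lambda) = \sum_k d_k \log \lambda_k - E_k \lambda_k} where
#' \eqn{d_k} and \eqn{E_k} are the per-interval events and exposure. This is
#' identical to the per-subject sum
#' \eqn{\sum_i d_i \log h(t_i) - H(t_i)}.
#'
#' @param lambda Vector of positive interval hazards, one per interval.
#' @param data A [surv_data()] object.
#' @param cutpoints Cut points as for [interval_counts()].
#' @return The log-likelihood value.
#' @export
piecewise_loglik <- function(lambda, data, cutpoints) {
  cnt <- interval_counts(data, cutpoints)
  if (length(lambda) != nrow(cnt))
    stop("need one hazard per interval")
  sum(cnt$events * log(lambda) - cnt$exposure * lambda)
}

rw_model_string <- function(rw_order) {
  prior <- if (rw_order == 1) "
  loglam[1] ~ dnorm(0, 1.0E-2)
  for (k in 2:K) { loglam[k] ~ dnorm(loglam[k-1], tau) }"
  else "
  loglam[1] ~ dnorm(0, 1.0E-2)
  loglam[2] ~ dnorm(loglam[1], 1.0E-2)
  for (k in 3:K) { loglam[k] ~ dnorm(2 * loglam[k-1] - loglam[k-2], tau) }"
  paste0("model {
  for (k in 1:K) {
    events[k] ~ dpois(exposure[k] * exp(loglam[k]))
  }", prior, "
  tau ~ dgamma(0.01, 0.01)
}")
}

#' Fit the Bayesian piecewise-exponential hazard model
#'
#' Fits constant hazards \eqn{\lambda_1, \ldots, \lambda_K} on the intervals
#' defined by `cutpoints` under the piecewise-exponential likelihood, with a
#' Gaussian random-walk prior of order 1 or 2 on the log-hazards: increments
#' of `log(lambda)` (first or second differences) are Gaussian with mean
#' zero and a common precision, itself given a vague Gamma(0.01, 0.01)
#' hyperprior. Sampling is MCMC via JAGS; two chains are run with
#' seed-derived generators so results are exactly reproducible, and
#' convergence is summarised by the Gelman-Rubin statistic and effective
#' sample sizes (a warning is raised when the largest potential scale
#' reduction factor exceeds 1.1).
#'
#' @param data A [surv_data()] object with at least one event.
#' @param cutpoints Interval cut points, e.g. from [make_cutpoints()].
#' @param rw_order Order of the random walk smoothing prior, 1 or 2.
#' @param n_draws Total number of posterior draws to retain (>= 100).
#' @param seed Integer seed; chains use seeds `seed + 1` and `seed + 2`.
#' @param n_burnin Burn-in iterations per chain.
#' @return An object of class `"piecewise_fit"` with components `cutpoints`,
#'   `log_hazard_draws` (draws x segments), `rw_precision_draws`,
#'   `rw_order`, `n_fitted` (number of segments informed by data, as opposed
#'   to appended by [extend_posterior()]) and `diagnostics`.
#' @export
fit_piecewise <- function(data, cutpoints, rw_order = 1, n_draws = 2000,
                          seed = 1, n_burnin = 1000) {
  stopifnot(is_surv_data(data), rw_order %in% c(1, 2), n_draws >= 100)
  if (sum(data$event) == 0)
    stop("no events in the data; the hazard is not identified")
  cnt <- interval_counts(data, cutpoints)
  K <- nrow(cnt)
  n_chains <- 2L
  per_chain <- ceiling(n_draws / n_chains)
  inits <- lapply(seq_len(n_chains), function(i) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = as.integer(seed) + i)
  })
  jm <- rjags::jags.model(
    textConnection(rw_model_string(rw_order)),
    data = list(K = K, events = cnt$events, exposure = cnt$exposure),
    inits = inits, n.chains = n_chains, quiet = TRUE)
  stats::update(jm, n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("loglam", "tau"), n.iter = per_chain,
                              progress.bar = "none")
  psrf <- tryCatch(
    max(coda::gelman.diag(samp, multivariate = FALSE)$psrf[, "Point est."],
        na.rm = TRUE),
    error = function(e) NA_real_)
  mat <- do.call(rbind, lapply(samp, as.matrix))
  mat <- mat[seq_len(min(n_draws, nrow(mat))), , drop = FALSE]
  loglam <- mat[, paste0("loglam[", seq_len(K), "]"), drop = FALSE]
  colnames(loglam) <- paste0("seg", seq_len(K))
  ess <- coda::effectiveSize(coda::mcmc(mat))
  diagnostics <- list(max_psrf = psrf, min_ess = min(ess),
                      n_chains = n_chains, n_burnin = n_burnin)
  if (is.finite(psrf) && psrf > 1.1) {
    warn <- simpleWarning(sprintf(
      "piecewise fit may not have converged: max PSRF = %.3f", psrf))
    attr(warn, "diagnostics") <- diagnostics
    warning(warn)
  }
  structure(
    list(cutpoints = as.numeric(cutpoints),
         log_hazard_draws = loglam,
         rw_precision_draws = unname(mat[, "tau"]),
         rw_order = rw_order,
         n_fitted = K,
         counts = cnt,
         diagnostics = diagnostics,
         seed = as.integer(seed)),
    class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  K <- ncol(x$log_hazard_draws)
  cat(sprintf(
    "Bayesian piecewise-exponential fit: %d segments (%d fitted, %d extrapolated)\n",
    K, x$n_fitted, K - x$n_fitted))
  cat(sprintf("  RW order %d prior on log-hazards; %d posterior draws\n",
              x$rw_order, nrow(x$log_hazard_draws)))
  cat(sprintf("  max PSRF %.3f, min ESS %.0f\n",
              x$diagnostics$max_psrf, x$diagnostics$min_ess))
  invisible(x)
}

#' Extrapolate the piecewise posterior beyond follow-up
#'
#' Appends hazard segments up to `horizon`, forward-simulating the fitted
#' random walk on the log-hazard scale for every posterior draw: each
#' appended increment is Gaussian with mean implied by the RW order (last
#' value for order 1, linear continuation for order 2) and that draw's
#' posterior precision. Uncertainty therefore grows with extrapolation
#' distance.
#'
#' @param fit A `"piecewise_fit"`.
#' @param horizon Time (months) up to which segments are appended; must
#'   exceed the current last cut point.
#' @param segment_width Width of appended segments; defaults to the fitted
#'   interval width. The final segment is shortened if needed to land
#'   exactly on `horizon`.
#' @param seed Integer seed for the forward simulation.
#' @return A `"piecewise_fit"` with extended `cutpoints` and draws.
#' @export
extend_posterior <- function(fit, horizon, segment_width = NULL, seed = 1) {
  stopifnot(inherits(fit, "piecewise_fit"))
  last <- fit$cutpoints[length(fit$cutpoints)]
  if (horizon <= last)
    stop("horizon (", horizon, ") must exceed the last cutpoint (", last, ")")
  if (is.null(segment_width))
    segment_width <- mean(diff(fit$cutpoints[seq_len(fit$n_fitted + 1L)]))
  new_cuts <- seq(last, horizon, by = segment_width)[-1]
  if (!length(new_cuts) || new_cuts[length(new_cuts)] < horizon)
    new_cuts <- c(new_cuts, horizon)
  J <- length(new_cuts)
  L <- fit$log_hazard_draws
  n <- nrow(L)
  K <- ncol(L)
  sdev <- 1 / sqrt(fit$rw_precision_draws)
  set.seed(as.integer(seed))
  extra <- matrix(NA_real_, n, J)
  prev1 <- L[, K]
  prev2 <- if (K >= 2) L[, K - 1L] else L[, K]
  for (j in seq_len(J)) {
    mu <- if (fit$rw_order == 1) prev1 else 2 * prev1 - prev2
    # cap keeps exp() finite in downstream linear algebra; survival is
    # already exactly 0/1 far inside these bounds
    extra[, j] <- pmin(pmax(mu + stats::rnorm(n, 0, sdev), -300), 300)
    prev2 <- prev1
    prev1 <- extra[, j]
  }
  colnames(extra) <- paste0("seg", K + seq_len(J))
  fit$cutpoints <- c(fit$cutpoints, new_cuts)
  fit$log_hazard_draws <- cbind(L, extra)
  fit
}

# exposure of each segment k to [0, t_g]: K x G matrix of overlaps
segment_overlap <- function(cutpoints, grid) {
  K <- length(cutpoints) - 1L
  lo <- cutpoints[-(K + 1L)]
  hi <- cutpoints[-1L]
  out <- matrix(0, K, length(grid))
  for (k in seq_len(K)) {
    out[k, ] <- pmax(0, pmin(grid, hi[k]) - lo[k])
  }
  out
}

check_grid_within <- function(fit, grid) {
  grid <- as.numeric(grid)
  if (anyNA(grid) || any(grid < 0)) stop("grid times must be non-negative")
  last <- fit$cutpoints[length(fit$cutpoints)]
  if (any(grid > last))
    stop("grid extends beyond the last cutpoint (", last,
         "); use extend_posterior() first")
  grid
}

#' Posterior survival curves from a piecewise fit
#'
#' Per draw, the cumulative hazard is the piecewise-linear integral of the
#' step hazard and \eqn{S(t) = \exp(-H(t))}.
#'
#' @param fit A `"piecewise_fit"`.
#' @param grid Time grid within `[0, last cutpoint]`.
#' @return A [curve_draws()] of kind `"survival"`.
#' @export
survival_draws <- function(fit, grid) {
  stopifnot(inherits(fit, "piecewise_fit"))
  grid <- check_grid_within(fit, grid)
  H <- exp(fit$log_hazard_draws) %*% segment_overlap(fit$cutpoints, grid)
  curve_draws(grid, exp(-H), kind = "survival")
}

#' Posterior cumulative-hazard curves from a piecewise fit
#'
#' Direct piecewise-linear integration of the step hazard — numerically
#' preferable to `-log(S)` when survival underflows at long horizons.
#'
#' @inheritParams survival_draws
#' @return A [curve_draws()] of kind `"cumulative_hazard"`.
#' @export
cumhaz_draws <- function(fit, grid) {
  stopifnot(inherits(fit, "piecewise_fit"))
  grid <- check_grid_within(fit, grid)
  H <- exp(fit$log_hazard_draws) %*% segment_overlap(fit$cutpoints, grid)
  curve_draws(grid, H, kind = "cumulative_hazard")
}

#' Posterior hazard curves from a piecewise fit
#'
#' Step-function evaluation of the interval hazards, right-continuous at cut
#' points: a grid time exactly at `u[k]` returns the hazard of the interval
#' being entered, `lambda[k+1]` (except at the final cut point, which has no
#' following interval and returns the last hazard).
#'
#' @inheritParams survival_draws
#' @return A [curve_draws()] of kind `"hazard"`.
#' @export
hazard_draws <- function(fit, grid) {
  stopifnot(inherits(fit, "piecewise_fit"))
  grid <- check_grid_within(fit, grid)
  K <- ncol(fit$log_hazard_draws)
  idx <- pmin(pmax(findInterval(grid, fit$cutpoints), 1L), K)
  curve_draws(grid, exp(fit$log_hazard_draws)[, idx, drop = FALSE],
              kind = "hazard")
}
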