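# shared fixtures: everything is generated in code at test time

# fully observed exponential sample
exp_data <- function(n, rate, seed, censor = Inf) {
  simulate_trial(trial_scenario(n, "exponential", list(rate = rate),
                                admin_censor_time = censor, seed = seed))
}

# two-piece constant hazard: h1 before `split`, h2 after, admin censor
piecewise_exp_data <- function(n, h1, h2, split, censor, seed) {
  set.seed(seed)
  u <- stats::runif(n)
  h_total <- -log(u)
  t <- ifelse(h_total <= h1 * split,
              h_total / h1,
              split + (h_total - h1 * split) / h2)
  time <- pmin(t, censor)
  surv_data(time = time, event = as.numeric(t <= censor))
}

# a small deterministic piecewise_fit built by hand (no MCMC), for
# exercising the draw -> curve algebra with known hazards
fake_piecewise_fit <- function(log_lambda, cutpoints, n_draws = 5,
                               precision = Inf, rw_order = 1) {
  L <- matrix(rep(log_lambda, each = n_draws), nrow = n_draws)
  colnames(L) <- paste0("seg", seq_along(log_lambda))
  structure(
    list(cutpoints = cutpoints,
         log_hazard_draws = L,
         rw_precision_draws = rep(precision, n_draws),
         rw_order = rw_order,
         n_fitted = length(log_lambda),
         counts = NULL,
         diagnostics = list(max_psrf = 1, min_ess = n_draws),
         seed = 1L),
    class = "piecewise_fit")
}

# a parametric_fit with every draw pinned at given parameters
fake_parametric_fit <- function(family, params, n_draws = 5) {
  draws <- matrix(rep(unlist(params), each = n_draws), nrow = n_draws)
  colnames(draws) <- names(params)
  structure(
    list(family = family,
         point_estimate = unlist(params),
         parameter_draws = draws,
         loglik = NA_real_, n = 0L, n_events = 0L),
    class = "parametric_fit")
}

# a survival curve_draws ensemble with per-draw exponential decay
random_survival_ensemble <- function(n_draws, grid, rate_range = c(0.01, 0.1),
                                     seed = 1) {
  set.seed(seed)
  rates <- stats::runif(n_draws, rate_range[1], rate_range[2])
  curve_draws(grid, exp(-outer(rates, grid)), kind = "survival")
}

quiet_fit_piecewise <- function(...) suppressWarnings(fit_piecewise(...))
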