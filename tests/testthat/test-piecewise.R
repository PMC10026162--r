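test_that("make_cutpoints spaces intervals evenly and checks follow-up", {
  d <- surv_data(time = c(5, 47), event = c(1, 0))
  expect_equal(make_cutpoints(d, 8, 48), seq(0, 48, by = 6))
  expect_equal(make_cutpoints(surv_data(9, 1), 1, 10), c(0, 10))
  expect_equal(make_cutpoints(surv_data(8, 1), 3, 9), c(0, 3, 6, 9))
  expect_error(make_cutpoints(d, 4, 40), "larger value")
})

test_that("interval_counts does left-open right-closed person-time accounting", {
  d1 <- surv_data(5, 1)
  c1 <- interval_counts(d1, c(0, 3, 6))
  expect_equal(c1$events, c(0, 1))
  expect_equal(c1$exposure, c(3, 2))

  c2 <- interval_counts(surv_data(5, 0), c(0, 3, 6))
  expect_equal(c2$events, c(0, 0))
  expect_equal(c2$exposure, c(3, 2))

  # boundary event belongs to the interval it closes
  d3 <- surv_data(c(3, 3), c(1, 0))
  c3 <- interval_counts(d3, c(0, 3))
  expect_equal(c3$events, 1)
  expect_equal(c3$exposure, 6)

  expect_error(interval_counts(surv_data(7, 1), c(0, 3, 6)), "beyond")
})

test_that("exposure and events are conserved for random data and cutpoints", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    d <- surv_data(runif(n, 0.1, 90), rbinom(n, 1, 0.6))
    cuts <- c(0, sort(runif(sample(2:6, 1), 1, 90)), 95)
    cnt <- interval_counts(d, cuts)
    expect_equal(sum(cnt$exposure), sum(d$time))
    expect_equal(sum(cnt$events), sum(d$event))
  }
})

test_that("interval-count log-likelihood equals the per-subject sum", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(4:25, 1)
    d <- surv_data(runif(n, 0.1, 20), rbinom(n, 1, 0.7))
    cuts <- c(0, sort(runif(3, 1, 20)), 21)
    lam <- runif(length(cuts) - 1, 0.01, 0.5)
    # oracle: per-subject d_i log h(t_i) - H(t_i) with the step hazard
    H_i <- vapply(d$time, function(t)
      sum(lam * pmax(0, pmin(t, cuts[-1]) - cuts[-length(cuts)])),
      numeric(1))
    k_i <- findInterval(d$time, cuts, left.open = TRUE)
    oracle <- sum(d$event * log(lam[k_i]) - H_i)
    expect_equal(piecewise_loglik(lam, d, cuts), oracle, tolerance = 1e-12)
  }
})

test_that("posterior recovers a constant hazard and is seed-deterministic", {
  d <- exp_data(500, rate = 0.05, seed = 31, censor = 60)
  cuts <- make_cutpoints(d, 4, 60)
  fit <- quiet_fit_piecewise(d, cuts, n_draws = 1000, seed = 5)
  lam_hat <- colMeans(exp(fit$log_hazard_draws))
  expect_true(all(abs(lam_hat - 0.05) / 0.05 < 0.15))
  expect_true(is.finite(fit$diagnostics$max_psrf))

  fit2 <- quiet_fit_piecewise(d, cuts, n_draws = 1000, seed = 5)
  expect_identical(fit$log_hazard_draws, fit2$log_hazard_draws)
  expect_identical(fit$rw_precision_draws, fit2$rw_precision_draws)

  expect_error(fit_piecewise(surv_data(c(1, 2), c(0, 0)), c(0, 3)),
               "no events")
})

test_that("posterior detects a hazard doubling at the interval boundary", {
  d <- piecewise_exp_data(1000, h1 = 0.04, h2 = 0.08, split = 24,
                          censor = 48, seed = 77)
  fit <- quiet_fit_piecewise(d, c(0, 24, 48), n_draws = 1000, seed = 9)
  lam <- colMeans(exp(fit$log_hazard_draws))
  expect_gt(lam[2] / lam[1], 1.6)
  expect_lt(lam[2] / lam[1], 2.5)
})

test_that("posterior-mean error shrinks with sample size on average", {
  mae <- function(n, seed) {
    d <- exp_data(n, rate = 0.05, seed = seed, censor = 60)
    fit <- quiet_fit_piecewise(d, make_cutpoints(d, 4, 60),
                               n_draws = 400, seed = seed)
    mean(abs(colMeans(exp(fit$log_hazard_draws)) - 0.05))
  }
  seeds <- 1:20
  err_small <- vapply(seeds, function(s) mae(100, 1000 + s), numeric(1))
  err_large <- vapply(seeds, function(s) mae(2000, 2000 + s), numeric(1))
  expect_lt(mean(err_large), mean(err_small))
})

test_that("RW extrapolation appends segments with growing uncertainty", {
  d <- exp_data(300, rate = 0.04, seed = 17, censor = 48)
  fit <- quiet_fit_piecewise(d, make_cutpoints(d, 4, 48), n_draws = 500,
                             seed = 3)
  ext <- extend_posterior(fit, horizon = 60, seed = 4)
  expect_equal(length(ext$cutpoints), length(fit$cutpoints) + 1)
  expect_equal(max(ext$cutpoints), 60)
  expect_error(extend_posterior(fit, horizon = 48), "exceed")

  # degenerate RW: infinite precision pins extrapolation at the last value
  fk <- fake_piecewise_fit(log(c(0.05, 0.08)), c(0, 10, 20),
                           n_draws = 50, precision = Inf)
  fke <- extend_posterior(fk, horizon = 50, segment_width = 10, seed = 1)
  expect_equal(unname(fke$log_hazard_draws[, 3:5]),
               matrix(log(0.08), 50, 3))

  # order-1 forward variance grows as j / tau (fixed-precision ensemble
  # gives the clean Monte-Carlo check of the variance law)
  fk3 <- fake_piecewise_fit(log(0.05), c(0, 48), n_draws = 6000,
                            precision = 4)
  ext2 <- extend_posterior(fk3, horizon = 48 + 60, segment_width = 12,
                           seed = 8)
  dif <- ext2$log_hazard_draws[, 1 + (1:5), drop = FALSE] - log(0.05)
  v <- apply(dif, 2, var)
  expect_equal(unname(v), (1:5) / 4, tolerance = 0.1)
  expect_true(all(diff(v) > 0))
})

test_that("survival draws integrate the step hazard exactly", {
  fk <- fake_piecewise_fit(log(rep(0.1, 3)), c(0, 5, 10, 15), n_draws = 4)
  s <- survival_draws(fk, c(0, 10))
  expect_equal(unname(s$draws[, 1]), rep(1, 4))
  expect_equal(unname(s$draws[, 2]), rep(exp(-1), 4), tolerance = 1e-12)

  fk2 <- fake_piecewise_fit(log(c(0.1, 0.2)), c(0, 5, 10), n_draws = 3)
  s2 <- survival_draws(fk2, 8)
  expect_equal(unname(s2$draws[, 1]), rep(exp(-1.1), 3), tolerance = 1e-12)
  expect_error(survival_draws(fk2, c(0, 12)), "extend_posterior")
})

test_that("hazard draws are right-continuous steps consistent with survival", {
  fk <- fake_piecewise_fit(log(c(0.1, 0.25)), c(0, 5, 10), n_draws = 3)
  expect_equal(unname(hazard_draws(fk, 2)$draws[, 1]), rep(0.1, 3))
  expect_equal(unname(hazard_draws(fk, 5)$draws[, 1]), rep(0.25, 3))
  expect_equal(unname(hazard_draws(fk, 7)$draws[, 1]), rep(0.25, 3))

  # -d/dt log S matches the step hazard away from cutpoints
  d <- exp_data(200, rate = 0.06, seed = 23, censor = 40)
  fit <- quiet_fit_piecewise(d, make_cutpoints(d, 4, 40), n_draws = 200,
                             seed = 2)
  tt <- c(3, 12, 27, 36)
  h <- 1e-5
  s_hi <- survival_draws(fit, tt + h)$draws
  s_lo <- survival_draws(fit, tt - h)$draws
  fd <- -(log(s_hi) - log(s_lo)) / (2 * h)
  expect_equal(fd, hazard_draws(fit, tt)$draws, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("posterior mean survival stays inside the KM confidence band", {
  d <- exp_data(400, rate = 0.03, seed = 41, censor = 48)
  fit <- quiet_fit_piecewise(d, make_cutpoints(d, 6, 48), n_draws = 800,
                             seed = 6)
  t_last <- max(d$time[d$event == 1])
  s_hat <- mean(survival_draws(fit, t_last)$draws)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                  data = as.data.frame(d)), times = t_last)
  expect_gte(s_hat, sf$lower)
  expect_lte(s_hat, sf$upper)
})
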