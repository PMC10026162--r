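test_that("elicitation specs validate their constraints", {
  expect_error(elicitation_spec(data.frame(time = 120, survival = 0.2),
                                n_effective = 0, t_max = 300), "positive")
  expect_error(elicitation_spec(data.frame(time = 320, survival = 0.2),
                                n_effective = 10, t_max = 300),
               "between 0 and t_max")
  expect_error(elicitation_spec(data.frame(time = c(60, 120),
                                           survival = c(0.2, 0.5)),
                                n_effective = 10, t_max = 300),
               "decreasing")
  expect_error(elicitation_spec(data.frame(time = c(120, 60),
                                           survival = c(0.5, 0.2)),
                                n_effective = 10, t_max = 300),
               "increasing")
  expect_error(elicitation_spec(data.frame(time = 60, survival = 0),
                                n_effective = 10, t_max = 300), "\\(0, 1]")
})

test_that("pseudo-data bands carry the elicited mass with fully observed times", {
  spec <- elicitation_spec(data.frame(time = 120, survival = 0.20),
                           n_effective = 100, t_max = 300)
  pd <- build_pseudo_data(spec, seed = 2)
  expect_equal(nrow(pd), 100)
  expect_true(all(pd$event == 1))
  expect_equal(sum(pd$time <= 120), 80)
  expect_equal(sum(pd$time > 120), 20)
  expect_true(all(pd$time < 300))

  spec2 <- elicitation_spec(data.frame(time = 60, survival = 0.5),
                            n_effective = 2, t_max = 100)
  pd2 <- build_pseudo_data(spec2, seed = 3)
  expect_equal(sum(pd2$time < 60), 1)
  expect_equal(sum(pd2$time > 60), 1)

  spec3 <- elicitation_spec(data.frame(time = c(120, 180),
                                       survival = c(0.30, 0.10)),
                            n_effective = 100, t_max = 300)
  pd3 <- build_pseudo_data(spec3, seed = 4)
  expect_equal(attr(pd3, "band_counts")$count, c(70L, 20L, 10L))
})

test_that("largest-remainder rounding matches an independent allocation oracle", {
  # oracle: start from floors, then hand out leftovers one at a time to the
  # band whose current count is furthest below its exact share
  oracle <- function(mass, n) {
    cnt <- floor(n * mass)
    while (sum(cnt) < n) {
      deficit <- n * mass - cnt
      j <- which.max(deficit)
      cnt[j] <- cnt[j] + 1
    }
    as.integer(cnt)
  }
  set.seed(55)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    w <- rgamma(k, 1)
    mass <- w / sum(w)
    n <- sample(c(3, 10, 100, 301), 1)
    got <- blendsurv:::largest_remainder(mass, n)
    expect_equal(got, oracle(mass, n))
    expect_equal(sum(got), n)
  }
})

test_that("survivor fractions above each constraint are exact to 1/n", {
  set.seed(66)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    tt <- sort(runif(k, 10, 200))
    pp <- sort(runif(k, 0.02, 0.95), decreasing = TRUE)
    n <- sample(c(20, 100, 500), 1)
    spec <- elicitation_spec(data.frame(time = tt, survival = pp), n,
                             t_max = 250)
    pd <- build_pseudo_data(spec, seed = i)
    for (j in seq_len(k)) {
      expect_lte(abs(mean(pd$time > tt[j]) - pp[j]), 1 / n + 1e-12)
    }
  }
})

test_that("ML fits recover known parameters and are deterministic", {
  d <- exp_data(1000, rate = 0.02, seed = 12)
  fit <- fit_parametric(d, "exponential", n_draws = 100, seed = 1)
  expect_lt(abs(fit$point_estimate[["rate"]] - 0.02) / 0.02, 0.1)

  fit2 <- fit_parametric(d, "exponential", n_draws = 100, seed = 1)
  expect_identical(fit$parameter_draws, fit2$parameter_draws)

  # Gompertz nests the exponential: exact at shape = 0, continuous nearby
  grid <- seq(0, 120, by = 6)
  g0 <- fake_parametric_fit("gompertz", list(shape = 0, rate = 0.02), 2)
  expect_equal(parametric_survival(g0, grid)$draws[1, ],
               exp(-0.02 * grid), tolerance = 1e-12, ignore_attr = TRUE)
  geps <- fake_parametric_fit("gompertz", list(shape = 1e-10, rate = 0.02),
                              2)
  expect_equal(parametric_survival(geps, grid)$draws[1, ],
               exp(-0.02 * grid), tolerance = 1e-6, ignore_attr = TRUE)
  # and a Gompertz fitted to exponential data stays close to the
  # exponential fit (shape estimate differs from 0 only by sampling noise)
  gfit <- fit_parametric(d, "gompertz", n_draws = 100, seed = 1)
  s_exp <- exp(-fit$point_estimate[["rate"]] * grid)
  s_gom <- flexsurv::pgompertz(grid, gfit$point_estimate[["shape"]],
                               gfit$point_estimate[["rate"]],
                               lower.tail = FALSE)
  expect_lt(max(abs(s_gom - s_exp)), 0.02)

  expect_error(fit_parametric(surv_data(c(1, 2), c(1, 0)), "weibull"),
               "2 events")
})

test_that("parametric survival matches closed forms and quadrature", {
  f <- fake_parametric_fit("exponential", list(rate = 0.1), n_draws = 3)
  expect_equal(unname(parametric_survival(f, 10)$draws[, 1]),
               rep(exp(-1), 3))
  expect_equal(unname(parametric_survival(f, 0)$draws[, 1]), rep(1, 3))

  g <- fake_parametric_fit("gompertz", list(shape = 0.05, rate = 0.01),
                           n_draws = 2)
  s24 <- exp(-(0.01 / 0.05) * (exp(0.05 * 24) - 1))
  expect_equal(unname(parametric_survival(g, 24)$draws[, 1]), rep(s24, 2),
               tolerance = 1e-12)
  # quadrature of h(t) = mu * exp(gamma t) confirms the closed form
  Hq <- integrate(function(t) 0.01 * exp(0.05 * t), 0, 24)$value
  expect_equal(s24, exp(-Hq), tolerance = 1e-8)

  for (fam in c("weibull", "lognormal", "loglogistic")) {
    pars <- switch(fam,
      weibull = list(shape = 1.5, scale = 50),
      lognormal = list(meanlog = 3.5, sdlog = 0.8),
      loglogistic = list(shape = 2, scale = 40))
    ff <- fake_parametric_fit(fam, pars, n_draws = 2)
    s <- parametric_survival(ff, c(0, 20, 60))
    expect_equal(unname(s$draws[1, 1]), 1)
    expect_true(all(diff(s$draws[1, ]) < 0))
  }
})

test_that("parametric hazards agree with -dlogS/dt and family facts", {
  f <- fake_parametric_fit("exponential", list(rate = 0.1), n_draws = 2)
  expect_equal(unname(parametric_hazard(f, c(1, 50))$draws[1, ]),
               c(0.1, 0.1))

  w1 <- fake_parametric_fit("weibull", list(shape = 1, scale = 25),
                            n_draws = 2)
  expect_equal(unname(parametric_hazard(w1, c(2, 9, 80))$draws[1, ]),
               rep(1 / 25, 3))

  g <- fake_parametric_fit("gompertz", list(shape = 0.04, rate = 0.01),
                           n_draws = 2)
  hg <- parametric_hazard(g, seq(1, 100, by = 5))$draws[1, ]
  expect_true(all(diff(hg) > 0))

  for (fam in c("gompertz", "weibull", "lognormal", "loglogistic")) {
    pars <- switch(fam,
      gompertz = list(shape = 0.03, rate = 0.008),
      weibull = list(shape = 1.4, scale = 60),
      lognormal = list(meanlog = 4, sdlog = 0.7),
      loglogistic = list(shape = 2.2, scale = 45))
    ff <- fake_parametric_fit(fam, pars, n_draws = 2)
    tt <- c(5, 20, 45, 90)
    h <- 1e-5
    s_hi <- parametric_survival(ff, tt + h)$draws[1, ]
    s_lo <- parametric_survival(ff, tt - h)$draws[1, ]
    fd <- -(log(s_hi) - log(s_lo)) / (2 * h)
    expect_equal(unname(parametric_hazard(ff, tt)$draws[1, ]), fd,
                 tolerance = 1e-4)
    # direct cumulative hazard equals -log S
    expect_equal(unname(parametric_cumhaz(ff, tt)$draws[1, ]),
                 -log(parametric_survival(ff, tt)$draws[1, ]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("larger effective sample sizes tighten the external band", {
  width_at <- function(n_eff, seed) {
    spec <- elicitation_spec(data.frame(time = 120, survival = 0.2),
                             n_effective = n_eff, t_max = 300)
    pd <- build_pseudo_data(spec, seed = seed)
    fit <- fit_parametric(pd, "gompertz", n_draws = 400, seed = seed)
    s <- summary(parametric_survival(fit, c(60, 120)))
    s$upper[2] - s$lower[2]
  }
  seeds <- 1:4
  w <- sapply(c(10, 100, 500), function(n_eff)
    mean(vapply(seeds, function(s) width_at(n_eff, s), numeric(1))))
  expect_true(all(diff(w) <= 0))
})
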