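# blendsurv

Blended survival curves for long-term extrapolation of censored
time-to-event data.

Cost-effectiveness analysis needs lifetime survival estimates, but trials
deliver a few years of follow-up and — in oncology especially — heavy
censoring. Extrapolating a single parametric fit decades past the data lets
the tail of an essentially arbitrary distribution drive the decision.
`blendsurv` implements the blended-curve alternative: fit the observed
period with a flexible Bayesian piecewise-exponential model (random-walk
smoothing prior on the log-hazards), build a separate external parametric
curve from hard long-term data or expert elicitation, and merge the two
through a time-varying weight

S_ble(t) = S_obs(t)^(1 − π(t)) · S_ext(t)^π(t),
  π(t) = F_Beta((t − a)/(b − a); α, β),

so the estimate equals the data-driven curve during follow-up (t ≤ a),
equals the external curve in the long run (t ≥ b), and moves smoothly
between them over the blending interval [a, b]. The same weight gives a
closed-form blended hazard whose extra term
f_Beta((t−a)/(b−a))/(b−a) · (H_ext − H_obs) permits turning points after
follow-up ends — something no monotone-hazard parametric extrapolation can
produce. Everything is carried as posterior/bootstrap draw ensembles, so
every curve comes with credible intervals.

The package is aimed at statisticians building health-technology-assessment
survival models: it reads plain `time,event` IPD, translates elicited
statements ("20 of 100 patients would survive beyond 10 years") into
synthetic datasets, fits five parametric families (exponential, Weibull,
Gompertz with h(t) = μ·exp(γt), log-normal, log-logistic), and ships a
simulation module with known truth for validation.

## Worked example

```r
library(blendsurv)

# trial-like IPD with heavy censoring at 48 months
ipd <- simulate_trial(trial_scenario(
  n = 400, family = "weibull", params = list(shape = 1.5, scale = 161),
  admin_censor_time = 48, dropout_rate = 0.002, seed = 42))

# expert elicitation: 30% alive at 10 y, 5% at 15 y, nobody beyond 30 y
elic <- elicitation_spec(
  data.frame(time = c(120, 180), survival = c(0.30, 0.05)),
  n_effective = 300, t_max = 360)

# linear blend from end of follow-up to the 15-year horizon
ws <- weight_spec(alpha = 1, beta = 1, blend_start = 48, blend_end = 180,
                  horizon = 180)

fit <- blendsurv(ipd, elic, ws, family = "gompertz", n_intervals = 8,
                 follow_up_end = 48, n_draws = 2000, seed = 42)
fit
#> Blended survival model
#>   Trial data: 400 subjects, 58 events (85.5% censored)
#>   Observed component: piecewise exponential, 8 intervals, RW1 prior
#>   External component: gompertz fit (300 subjects)
#>   Blending: Beta(1, 1) weight over [48, 180] months, horizon 180

summary(fit, times = c(48, 120, 180))
#> Survival summaries (mean and 95% credible interval)
#>     curve time   mean     lower  upper
#>   blended   48 0.8442 8.070e-01 0.8810
#>   blended  120 0.3996 4.021e-02 0.5033
#>   blended  180 0.1254 9.709e-02 0.1555
#>  observed   48 0.8442 8.070e-01 0.8810
#>  observed  120 0.5672 3.343e-03 0.8110
#>  observed  180 0.4204 2.914e-15 0.7913
#>  external   48 0.6908 6.522e-01 0.7287
#>  external  120 0.3180 2.740e-01 0.3596
#>  external  180 0.1254 9.709e-02 0.1555
```

Read the rows at 180 months: the observed-data model alone would report 42%
mean survival at 15 years with an interval spanning essentially (0, 0.79) —
the random-walk extrapolation is honest about knowing nothing out there.
The blended curve agrees with it exactly during follow-up (rows at 48
months are identical) and hands over to the expert-informed Gompertz in the
long term, ending at 12.5% (9.7–15.6%). `plot(fit)` and
`plot(fit, "hazard")` draw the three curves with bands and the Kaplan-Meier
overlay; `predict(fit, newtimes, type = "hazard")` evaluates at arbitrary
times.

A YAML-driven pipeline (`run_pipeline()`, config documented in
`?read_run_config`) writes summary tables, optional draw matrices, plots
and a provenance log; `inst/cli/blendsurv.R` is a thin command-line
front-end with `simulate`, `fit-observed`, `elicit`, `blend` and `run`
subcommands.

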