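# survlc

Survival learning curves with shared gamma frailty and restricted mean
survival time.

## The problem

Time-to-event outcomes after a surgical procedure — such as time from
placement of an external ventricular drain (EVD) to death or to a first
complication in hemorrhagic-stroke patients — are clustered: every
operator contributes many procedures, and operators differ in ways the
recorded covariates do not capture.  Two questions follow.  First, how
should covariate effects be estimated when this *provider heterogeneity*
is present?  Second, how does an operator's predicted probability of
procedural success change with cumulative case volume — the surgical
*learning curve* — and which parametric shape describes it best?

`survlc` is a toolkit for both questions, aimed at biostatisticians
studying clustered surgical outcomes.  Because real multicenter EVD data
are proprietary, the package ships a fully seeded synthetic cohort
generator that emulates such data, and a factorial simulation engine for
stress-testing the learning-curve machinery.

## The models

**Shared gamma frailty Cox.**  Procedures of operator *j* share an
unobserved multiplicative hazard effect *w<sub>j</sub>*:

    Λ_ij(t | w_j, x_ij) = w_j · Λ0(t) · exp(β' x_ij),   w_j ~ Gamma(mean 1, variance θ)

fit by EM (E-step posterior frailties `E[w_j] = (1/θ + D_j)/(1/θ + H_j)`,
M-step Cox fit with log-frailty offsets, Breslow baseline) with θ from a
profiled marginal likelihood; the frailty p-value is a boundary
likelihood-ratio test against the 50:50 χ²₀/χ²₁ mixture null.

**Restricted mean survival time.**  `RMST(τ) = ∫₀^τ S(u) du`, from the
Kaplan–Meier curve (with Greenwood-type standard error), from a frailty
baseline averaged over fitted frailties, or as a τ-truncated frailty
regression.  Group differences get cluster-bootstrap intervals.

**Learning curves.**  Four parametric shapes (exponential, power series,
logarithmic, log-normal) link success probability to case volume.  The
pipeline derives steady-state per-subject success probabilities `p0` from
a backend survival model without order terms, physician-level smoothed
probabilities `p1` from a refit with an ordered procedure variable,
center-level probabilities `p2` at cumulative center volume, and the
learning-adjusted survival times `tnew_i = (p2_i / p0_i) · time_i`, which
feed one final refit.  Backends: clustered Cox, frailty Cox, RMST
frailty, and a random survival forest (via `ranger`, out-of-bag).

## Worked example

```r
library(survlc)

cfg <- scenario_config(true_shape = "logarithmic", seed = 11)
cfg
#> Scenario: 4 centers x 10 physicians x 25 cases, logarithmic learning,
#>   10% censoring, theta=0.25, seed=11

co <- generate_cohort(cfg)
mean(co$event == 0)          # realized censoring, target 10%
#> [1] 0.089

fit <- fit_frailty(co, c("age", "smoke", "anticoagulant", "mrs"),
                   cluster = "operator_id")
fit
#> Shared gamma-frailty Cox model: theta = 0.3505 (frailty p = 4.99e-48), 40 clusters
#>                  coef     HR     se
#> age            0.0295 1.0299 0.0024
#> smoke          0.7601 2.1385 0.0690
#> anticoagulant  0.0416 1.0425 0.0718
#> mrs           -0.0140 0.9861 0.0219

lc <- run_lc_pipeline(co, backend = "cox", kind = "logarithmic")
lc
#> Learning-curve result: backend cox, shape logarithmic, horizon 30 d
#>   mean p0 0.551 | mean p1 0.550 | mean p2 0.550 | 5 bins
#> MSE1 0.0030 | MSE2 0.0225 | MSE2_a 0.0205 | MSE2_b 0.0000

rmst_km(km_estimate(co$time, co$event), 60)
#> RMST(tau = 60) = 35.8620 days (se 0.7122)
```

Reading the output: the generator embedded a hazard ratio of 2 for
smoking and 3% per year of age, and an operator frailty variance of 0.25
— the fit recovers HR 2.14 for smoking, 1.03/year for age, and θ̂ = 0.35
with a decisive frailty test.  The learning-curve result says the average
30-day success probability is about 0.55; `MSE1` measures how closely the
fitted logarithmic curve tracks the binned observed success rates, and
`MSE2`/`MSE2_a`/`MSE2_b` compare the steady-state, physician and center
probability levels.  The restricted mean says patients survive on average
35.9 of the first 60 days.

The factorial study over all 16 scenarios (operator counts × censoring ×
shape) runs with `run_study(scenario_grid(), ...)`, or from the shell via
the bundled CLI (`inst/scripts/survlc`): `simulate`, `fit`, `lc` and
`study` subcommands; `study` writes `table6_grid.csv`, `table7_mse.csv`,
`table8_levels.csv` and a JSON metadata record.

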