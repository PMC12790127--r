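test_that("RMST step integrals match hand calculations", {
  one <- km_estimate(5, 1)
  expect_error(rmst_km(one, 10), "horizon")
  expect_equal(rmst_km(one, 5)$estimate, 5)

  cv <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  # 1*1 + (2/3)*1 + (1/3)*1 = 2 = mean(T)
  expect_equal(rmst_km(cv, 3)$estimate, 2)

  censored <- km_estimate(c(4, 9), c(0, 0))
  expect_equal(rmst_km(censored, 9)$estimate, 9)
})

test_that("uncensored RMST at the last time equals the sample mean", {
  set.seed(7)
  t <- stats::rexp(150, 0.08)
  cv <- km_estimate(t, rep(1, 150))
  expect_equal(rmst_km(cv, max(t))$estimate, mean(t), tolerance = 1e-10)
})

test_that("RMST is non-decreasing in tau and bounded by tau", {
  set.seed(8)
  t <- stats::rexp(80, 0.05)
  e <- stats::rbinom(80, 1, 0.7)
  cv <- km_estimate(t, e)
  taus <- stats::quantile(t, c(0.2, 0.4, 0.6, 0.8))
  vals <- vapply(taus, function(tau) rmst_km(cv, tau)$estimate, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= taus))
})

test_that("RMST point estimate and Greenwood se match the survival package", {
  set.seed(3)
  t <- stats::rexp(50, 0.1)
  e <- stats::rbinom(50, 1, 0.8)
  mine <- rmst_km(km_estimate(t, e), 15)
  sm <- survival:::survmean(survival::survfit(survival::Surv(t, e) ~ 1),
                            rmean = 15)$matrix
  expect_equal(mine$estimate, unname(sm["rmean"]), tolerance = 1e-10)
  expect_equal(mine$se, unname(sm["se(rmean)"]), tolerance = 1e-10)
})

test_that("frailty-baseline RMST reduces to the baseline curve integral", {
  co <- small_cohort(seed = 13)
  fit <- fit_frailty(co, c("age", "smoke"), "operator_id", theta = 0)
  tau <- stats::quantile(co$time, 0.5)
  direct <- rmst_km(baseline_survival(fit), tau)$estimate
  expect_equal(rmst_frailty(fit, tau)$estimate, direct, tolerance = 1e-6)
})

test_that("larger linear predictor gives smaller restricted mean", {
  co <- small_cohort(seed = 13)
  fit <- fit_frailty(co, c("age", "smoke"), "operator_id", theta = 0)
  tau <- stats::quantile(co$time, 0.5)
  r_low <- rmst_frailty(fit, tau, covariates = c(age = 40, smoke = 0))
  r_high <- rmst_frailty(fit, tau, covariates = c(age = 80, smoke = 1))
  expect_gt(r_low$estimate, r_high$estimate)
})

test_that("exponential cohort RMST matches the closed form", {
  mu <- 1 / 40
  set.seed(17)
  t <- stats::rexp(4000, mu)
  cv <- km_estimate(t, rep(1, 4000))
  tau <- 60
  r <- rmst_km(cv, tau)
  expect_lt(abs(r$estimate - (1 - exp(-mu * tau)) / mu), 3 * r$se)
})

test_that("RMST difference: symmetry, doubling oracle, determinism", {
  co <- small_cohort(seed = 23)
  co$grp <- rep(c("A", "B"), length.out = nrow(co))
  # identical groups by construction of a mirrored cohort
  mirror <- rbind(co, co)
  mirror$grp <- rep(c("A", "B"), each = nrow(co))
  mirror$operator_id <- rep(1:2, each = nrow(co))
  tau <- stats::quantile(co$time, 0.5)
  same <- rmst_difference(mirror, "grp", tau, n_boot = 50, seed = 1)
  expect_equal(same$estimate, 0, tolerance = 1e-12)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  # group B = group A with all times doubled; oracle by direct integration
  a <- co[1:200, ]
  b <- a
  b$time <- 2 * a$time
  both <- rbind(a, b)
  both$grp <- rep(c("A", "B"), each = 200)
  kma <- km_estimate(a$time, a$event)
  kmb <- km_estimate(b$time, b$event)
  oracle <- rmst_km(kma, tau)$estimate - rmst_km(kmb, tau)$estimate
  est <- rmst_difference(both, "grp", tau, n_boot = 1, seed = 9)
  expect_equal(est$estimate, oracle, tolerance = 1e-12)

  again <- rmst_difference(both, "grp", tau, n_boot = 1, seed = 9)
  expect_identical(est$ci, again$ci)
})

test_that("tau-truncation refit: no-op, degenerate and recovery behaviour", {
  co <- small_cohort(seed = 31, theta = 0.5)
  full <- fit_frailty(co, c("age", "smoke"), "operator_id")
  notrunc <- fit_rmst_frailty_regression(co, c("age", "smoke"),
                                         "operator_id",
                                         tau = max(co$time) + 1)
  expect_equal(notrunc$beta, full$beta, tolerance = 1e-8)
  expect_error(
    fit_rmst_frailty_regression(co, c("age", "smoke"), "operator_id",
                                tau = min(co$time[co$event == 1]) / 2),
    "no events"
  )
  trunc <- fit_rmst_frailty_regression(co, c("age", "smoke"),
                                       "operator_id",
                                       tau = stats::quantile(co$time, 0.75))
  # truncation keeps the sign and order of magnitude of the smoking effect
  expect_gt(unname(trunc$beta["smoke"]), 0)
  expect_lt(abs(unname(trunc$beta["smoke"]) - log(2)), 0.7)
})
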