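test_that("Kaplan-Meier matches hand-computed product limits", {
  cv <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2: risk set of 1 at t = 3
  cv2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv2$surv[cv2$time == 1], 2 / 3)
  expect_equal(cv2$surv[cv2$time == 3], 0)
  # all censored: curve identically 1
  cv3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cv3$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring reproduces the empirical survivor function", {
  set.seed(9)
  t <- stats::rexp(200, 0.1)
  cv <- km_estimate(t, rep(1, 200))
  ecdf_surv <- 1 - stats::ecdf(t)(cv$time)
  expect_equal(cv$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank test: symmetry, hand value and label invariance", {
  g <- rep(c("A", "B"), each = 3)
  t <- c(1, 2, 3, 1, 2, 3)
  e <- c(1, 0, 1, 1, 0, 1)
  sym <- logrank_test(g, t, e)
  expect_equal(sym$statistic, 0, tolerance = 1e-12)
  expect_equal(sym$p_value, 1, tolerance = 1e-12)

  # 4-subject worked example: U = 2 - (1/2 + 1/3), V = 1/4 + 2/9
  lr <- logrank_test(c("A", "A", "B", "B"), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-10)

  perm <- c(3, 1, 4, 2)
  lr2 <- logrank_test(c("A", "A", "B", "B")[perm], c(1, 2, 3, 4)[perm],
                      rep(1, 4))
  expect_equal(lr2$statistic, lr$statistic)
  expect_error(logrank_test(rep("A", 4), c(1, 2, 3, 4), rep(1, 4)),
               "two groups")
})

test_that("Cox fit solves the 3-subject score equation", {
  d <- data.frame(time = c(1, 2, 3), event = 1, x = c(1, 0, 1))
  fit <- fit_cox(d, "x")
  expect_equal(unname(fit$beta), -log(2) / 2, tolerance = 1e-6)
  # independent brute-force oracle on the partial likelihood
  oracle <- grid_cox_beta(d$time, d$event, d$x)
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
})

test_that("degenerate Cox designs are rejected; null effects are null", {
  d <- data.frame(time = 1:5, event = 1, x = 1)
  expect_error(fit_cox(d, "x"), "constant")
  set.seed(12)
  dn <- data.frame(time = stats::rexp(400, 0.1),
                   event = rep(1L, 400), x = stats::rbinom(400, 1, 0.5))
  fit <- fit_cox(dn, "x")
  expect_lt(abs(fit$beta / fit$se_naive), 3)
})

test_that("Breslow baseline: increments, monotonicity and the 1/n case", {
  # one event among n identical subjects at t*
  n <- 7
  d <- data.frame(time = c(3, rep(5, n - 1)), event = c(1, rep(0, n - 1)))
  b <- breslow_cumhaz(d$time, d$event, rep(0, n))[["all"]]
  expect_equal(b$cumhaz, 1 / n)
  co <- small_cohort(seed = 6)
  fit <- fit_cox(co, c("age", "smoke"))
  base <- fit$baseline[["all"]]
  expect_true(all(diff(base$cumhaz) > 0))
  expect_equal(base$time, sort(unique(co$time[co$event == 1])))
})

test_that("null-model baseline survival equals exp(-Nelson-Aalen)", {
  set.seed(2)
  t <- stats::rexp(100, 0.05)
  e <- stats::rbinom(100, 1, 0.8)
  b <- breslow_cumhaz(t, e, rep(0, 100))[["all"]]
  na <- survival::survfit(survival::Surv(t, e) ~ 1, stype = 2, ctype = 1)
  expect_equal(b$cumhaz, na$cumhaz[na$n.event > 0], tolerance = 1e-12)
})

test_that("predicted survival follows the power relation", {
  fake <- structure(
    list(beta = c(x = log(2)), covariates = "x",
         baseline = list(all = data.frame(time = 10, haz = -log(0.8),
                                          cumhaz = -log(0.8))),
         frailties = NULL, cluster_var = NULL),
    class = "cox_fit"
  )
  expect_equal(predict_survival(fake, data.frame(x = 0), 10), 0.8)
  expect_equal(predict_survival(fake, data.frame(x = 1), 10), 0.8^2)
  # monotone: larger linear predictor, smaller survival
  p <- predict_survival(fake, data.frame(x = c(0, 0.5, 1, 2)), 10)
  expect_true(all(diff(p) < 0))
  expect_warning(predict_survival(fake, data.frame(x = 0), 99), "support")
})

test_that("frailty fit with theta = 0 reduces to the Cox fit", {
  co <- small_cohort(seed = 21)
  f0 <- fit_frailty(co, c("age", "smoke"), "operator_id", theta = 0)
  fc <- fit_cox(co, c("age", "smoke"))
  expect_equal(f0$beta, fc$beta, tolerance = 1e-6)
  expect_true(all(f0$frailties == 1))
  expect_equal(f0$frailty_pvalue, 1)
})

test_that("posterior frailties approach 1 as theta approaches 0", {
  co <- small_cohort(seed = 21)
  f <- fit_frailty(co, c("age", "smoke"), "operator_id", theta = 1e-6)
  expect_lt(max(abs(f$frailties - 1)), 1e-3)
})

test_that("fitted frailties satisfy the mean-1 constraint", {
  co <- small_cohort(seed = 33, theta = 0.5)
  f <- fit_frailty(co, c("age", "smoke"), "operator_id")
  expect_lt(abs(mean(f$frailties) - 1), 1e-6)
  expect_gte(f$theta, 0)
})

test_that("EM frailty fit agrees with coxph's penalized gamma frailty", {
  # same model, different outer criterion for theta; coefficients and
  # cluster effects must agree closely
  cfg <- scenario_config(theta_true = 0.5, physicians_per_center = 10,
                         n_centers = 3, cases_per_physician = 40,
                         censoring_target = 0.10, seed = 21)
  co <- generate_cohort(cfg)
  mine <- fit_frailty(co, c("age", "smoke"), "operator_id")
  ref <- survival::coxph(
    survival::Surv(time, event) ~ age + smoke +
      survival::frailty(operator_id, dist = "gamma"),
    data = co
  )
  expect_equal(unname(mine$beta), unname(stats::coef(ref)),
               tolerance = 0.02)
  expect_gt(stats::cor(log(mine$frailties), ref$frail), 0.99)
  expect_gt(mine$theta, 0.1)
  expect_lt(mine$theta, 1.5)
})

test_that("frailty fit needs at least two clusters", {
  co <- small_cohort(seed = 2)
  co$one <- 1
  expect_error(fit_frailty(co, c("age", "smoke"), "one"), "two clusters")
})
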