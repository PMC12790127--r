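test_that("identical config and seed give byte-identical cohorts", {
  cfg <- scenario_config(seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("cohort bookkeeping: nesting and case-order bijection", {
  co <- generate_cohort(scenario_config(n_centers = 4,
                                        physicians_per_center = 10,
                                        cases_per_physician = 25,
                                        seed = 3))
  expect_equal(nrow(co), 1000)
  expect_equal(length(unique(co$operator_id)), 40)
  for (op in split(co, co$operator_id)) {
    expect_equal(sort(op$case_order), 1:25)
    expect_equal(unique(op$center_id), op$center_id[1])
  }
  # center volume is a bijection onto 1..n within each center
  for (ce in split(co, co$center_id)) {
    expect_equal(sort(ce$center_order), seq_len(nrow(ce)))
  }
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
})

test_that("homogeneous no-learning cohort has exponential event times", {
  cfg <- scenario_config(
    physicians_per_center = 10, cases_per_physician = 250,
    censoring_target = 0, beta_true = numeric(0), theta_true = 0,
    true_shape_params = multiplier_spec("logarithmic", p_start = exp(-1),
                                        rate = 0, ref_cumhaz = 1),
    seed = 5
  )
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 10000)
  ks <- suppressWarnings(stats::ks.test(co$time, stats::pexp, rate = 1 / 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("operator frailties have mean 1 and variance theta_true", {
  cfg <- scenario_config(n_centers = 50, physicians_per_center = 5,
                         cases_per_physician = 1, theta_true = 0.5,
                         seed = 8)
  w <- attr(generate_cohort(cfg), "frailties")
  J <- length(w)
  expect_equal(J, 250)
  # 3 standard errors: se(mean) = sqrt(theta/J); se(var) ~ theta*sqrt(2/J)
  expect_lt(abs(mean(w) - 1), 3 * sqrt(0.5 / J))
  expect_lt(abs(stats::var(w) - 0.5), 3 * 0.5 * sqrt(2 / J))
})

test_that("generated covariate marginals match the profile", {
  prof <- covariate_profile()
  co <- generate_cohort(scenario_config(seed = 14))  # n = 1000
  n <- nrow(co)
  for (nm in names(prof$binary_prevalences)) {
    p <- prof$binary_prevalences[[nm]]
    expect_lt(abs(mean(co[[nm]]) - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_lt(abs(mean(co$age) - prof$age_mean), 3 * prof$age_sd / sqrt(n))
})

test_that("censoring calibration hits 10% and 70% targets", {
  for (target in c(0.10, 0.70)) {
    co <- generate_cohort(scenario_config(
      physicians_per_center = 10, cases_per_physician = 50,
      censoring_target = target, seed = 19
    ))
    expect_equal(nrow(co), 2000)
    expect_lt(abs(mean(co$event == 0) - target), 0.03)
  }
})

test_that("calibration recovers the exponential-exponential closed form", {
  # events ~ Exp(mu), censoring ~ Exp(lambda): P(censored) =
  # lambda / (lambda + mu), so a 50% target implies lambda = mu
  mu <- 0.05
  set.seed(4)
  lam <- calibrate_censoring(function(n) stats::rexp(n, mu), 0.5,
                             n_calib = 5000)
  expect_equal(as.numeric(lam), mu, tolerance = 0.05)
  expect_error(calibrate_censoring(function(n) stats::rexp(n, mu), 1.2),
               "target")
})

test_that("learning multiplier anchors, monotonicity and asymptote", {
  for (k in shape_kinds()) {
    sp <- multiplier_spec(k, p_start = 0.4, p_plateau = 0.65, rate = 0.3)
    g <- true_learning_multiplier(sp, 1:100)
    tol <- if (k == "log_normal") 1e-2 else 1e-12
    expect_equal(g[1], -log(0.4) / 0.5, tolerance = tol)
    expect_true(all(diff(g) <= 1e-12))
    expect_gt(min(g), 0)
  }
  sp <- multiplier_spec("exponential", p_start = 0.4, p_plateau = 0.65,
                        rate = 0.5)
  expect_equal(true_learning_multiplier(sp, 1e5), -log(0.65) / 0.5,
               tolerance = 1e-10)
  # a baseline subject's survival at the reference horizon traces the
  # target probability curve exactly
  target <- shape_value(shape_spec("exponential", 0.65, 0.4, 0.5), 1:25)
  expect_equal(exp(-true_learning_multiplier(sp, 1:25) * 0.5), target,
               tolerance = 1e-9)
  flat <- multiplier_spec("logarithmic", p_start = 0.5, rate = 0)
  g_flat <- true_learning_multiplier(flat, c(1, 10, 1000))
  expect_equal(g_flat, rep(-log(0.5) / 0.5, 3))
  expect_error(true_learning_multiplier(sp, 0), "case order")
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_centers = 0), "positive")
  expect_error(scenario_config(theta_true = -0.1), "theta_true")
  expect_error(scenario_config(censoring_target = 1), "censoring_target")
  expect_error(covariate_profile(age_sd = 0), "age_sd")
  expect_error(covariate_profile(binary_prevalences = c(smoke = 1.4)),
               "prevalences")
  expect_error(multiplier_spec("exponential", p_start = 0.7,
                               p_plateau = 0.5), "p_plateau")
})

test_that("cohorts round-trip through CSV", {
  co <- small_cohort(seed = 2, phys = 5, cases = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$time, co$time)
  expect_equal(back$center_order, co$center_order)
  expect_s3_class(back, "lc_cohort")
})
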