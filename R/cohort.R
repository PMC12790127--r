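#' Covariate profile for synthetic cohorts
#'
#' Marginal distributions of the patient-level covariates used when
#' generating synthetic multicenter EVD-like cohorts: age is Normal, the
#' pre-operative Modified Rankin Score (MRS) is Normal truncated to
#' `[0, 6]`, and the remaining covariates are independent Bernoulli draws.
#' Defaults reflect a hemorrhagic-stroke EVD population: mean age 57.5
#' (sd 14.5), 48.8% smokers, 27.5% on anticoagulants, a 64/36 split between
#' bactericidal and non-antibiotic drain devices, and so on.
#'
#' @param age_mean,age_sd age distribution (years).
#' @param mrs_mean,mrs_sd pre-op MRS distribution (score points).
#' @param binary_prevalences named vector of Bernoulli prevalences in
#'   `[0, 1]`; names become cohort columns.
#' @return An object of class `covariate_profile`.
#' @export
covariate_profile <- function(age_mean = 57.5, age_sd = 14.5,
                              mrs_mean = 2.93, mrs_sd = 1.67,
                              binary_prevalences = c(
                                male = 0.506,
                                diabetes = 0.125,
                                stroke_history = 0.113,
                                hypertension = 0.344,
                                anticoagulant = 0.275,
                                smoke = 0.488,
                                cvd_history = 0.150,
                                sah = 0.525,
                                ivh = 0.406,
                                ich = 0.469,
                                device_bactericidal = 0.644
                              )) {
  if (age_sd <= 0) stop_invalid("age_sd must be > 0")
  if (mrs_sd <= 0) stop_invalid("mrs_sd must be > 0")
  if (is.null(names(binary_prevalences)) || any(names(binary_prevalences) == "")) {
    stop_invalid("binary_prevalences must be a named vector")
  }
  if (any(binary_prevalences < 0 | binary_prevalences > 1)) {
    stop_invalid("all prevalences must lie in [0,1]")
  }
  structure(
    list(age_mean = age_mean, age_sd = age_sd, mrs_mean = mrs_mean,
         mrs_sd = mrs_sd, binary_prevalences = binary_prevalences),
    class = "covariate_profile"
  )
}

#' Default true log-hazard coefficients for the generator
#'
#' Modest, clinically plausible effects: a hazard ratio of 2 for smoking and
#' 3% per year of age (age enters centered at the profile mean).  All other
#' covariates are generated but carry no true effect, so they act as noise
#' covariates in the fitted models.
#'
#' @return Named numeric vector on the log-hazard scale.
#' @export
default_beta <- function() {
  c(age_c = 0.03, smoke = log(2))
}

#' Learning multiplier specification anchored on a probability curve
#'
#' The simulated learning effect enters the data-generating process as a
#' multiplier `g(order)` on the hazard, derived from a target
#' probability-scale learning curve `s(order)` (one of the four shapes,
#' rising from `p_start` at the first case towards `p_plateau`):
#' `g(order) = -log(s(order)) / ref_cumhaz`, with `ref_cumhaz` the
#' reference baseline cumulative hazard (baseline rate times the
#' evaluation horizon).  A baseline subject's survival probability at the
#' reference horizon is then \emph{exactly} `s(order)`, so the predicted
#' survival against case order traces the named shape.
#'
#' @param kind shape family, see [shape_kinds()].
#' @param p_start success probability at the first case, in `(0, 1)`.
#' @param p_plateau asymptotic success probability, `>= p_start`.
#' @param rate learning rate of the probability curve (`>= 0`; 0 gives a
#'   constant, no-learning multiplier).  Default per family spans most of
#'   the `p_start`-to-`p_plateau` gap within about 25 cases.
#' @param mu,sigma log-normal location and spread.
#' @param ref_cumhaz reference cumulative hazard (default `0.5`, i.e. a
#'   baseline rate of 1/60 per day at a 30-day horizon).
#' @return An object of class `multiplier_spec`.
#' @export
multiplier_spec <- function(kind = shape_kinds(), p_start = 0.40,
                            p_plateau = 0.65, rate = NULL, mu = log(8),
                            sigma = 0.8, ref_cumhaz = 0.5) {
  kind <- match.arg(kind)
  if (p_start <= 0 || p_start >= 1) stop_invalid("p_start must be in (0,1)")
  if (p_plateau < p_start || p_plateau >= 1) {
    stop_invalid("p_plateau must lie in [p_start, 1)")
  }
  if (ref_cumhaz <= 0) stop_invalid("ref_cumhaz must be > 0")
  if (is.null(rate)) {
    rate <- switch(kind, exponential = 0.15, power_series = 0.7,
                   logarithmic = (p_plateau - p_start) / log(25),
                   log_normal = 0)
  }
  if (rate < 0) stop_invalid("rate must be >= 0")
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  structure(
    list(kind = kind, p_start = p_start, p_plateau = p_plateau,
         rate = rate, mu = mu, sigma = sigma, ref_cumhaz = ref_cumhaz),
    class = "multiplier_spec"
  )
}

#' True learning multiplier on the hazard
#'
#' Evaluates the data-generating hazard multiplier `g(order)`; decreasing
#' in case order (later cases have lower hazard, hence higher success),
#' with `g(1) = -log(p_start) / ref_cumhaz` and asymptotic floor
#' `-log(p_plateau) / ref_cumhaz`.
#'
#' @param spec a [multiplier_spec()].
#' @param order case order(s), `>= 1`.
#' @return Positive hazard multipliers.
#' @export
true_learning_multiplier <- function(spec, order) {
  stopifnot(inherits(spec, "multiplier_spec"))
  if (any(order < 1)) stop("case order must be >= 1")
  curve <- shape_spec(spec$kind, asymptote = spec$p_plateau,
                      start = spec$p_start, rate = spec$rate,
                      mu = spec$mu, sigma = spec$sigma)
  s <- pmin(1 - 1e-9, pmax(1e-9, shape_value(curve, order)))
  -log(s) / spec$ref_cumhaz
}

#' Simulation scenario configuration
#'
#' Bundles the design of one synthetic-cohort scenario: the multicenter
#' layout (centers x physicians x cases), the target censoring proportion,
#' the true learning-curve shape on the hazard, the true covariate effects,
#' the operator frailty variance, and the exponential baseline hazard.
#'
#' @param n_centers number of centers (default 4).
#' @param physicians_per_center operators per center (5 or 10 in the
#'   factorial scenarios).
#' @param cases_per_physician consecutive cases per operator (default 25).
#' @param censoring_target target censoring proportion in `(0, 1)`; set to 0
#'   to disable censoring.
#' @param true_shape learning-curve family of the true hazard multiplier.
#' @param true_shape_params optional [multiplier_spec()]; defaults to the
#'   family's standard multiplier (start 2, floor 1).
#' @param beta_true named log-hazard coefficients (see [default_beta()]).
#' @param theta_true operator gamma-frailty variance (`>= 0`).
#' @param center_theta optional center-level frailty variance (default 0).
#' @param baseline_rate exponential baseline hazard, events per day.
#' @param seed integer RNG seed controlling the whole cohort draw.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_centers = 4, physicians_per_center = 10,
                            cases_per_physician = 25,
                            censoring_target = 0.10,
                            true_shape = shape_kinds(),
                            true_shape_params = NULL,
                            beta_true = default_beta(),
                            theta_true = 0.25,
                            center_theta = 0,
                            baseline_rate = 1 / 60,
                            seed = 1L) {
  true_shape <- match.arg(true_shape)
  if (n_centers < 1 || physicians_per_center < 1 || cases_per_physician < 1) {
    stop_invalid("counts must be positive")
  }
  if (censoring_target < 0 || censoring_target >= 1) {
    stop_invalid("censoring_target must lie in [0, 1)")
  }
  if (theta_true < 0) stop_invalid("theta_true must be >= 0")
  if (center_theta < 0) stop_invalid("center_theta must be >= 0")
  if (baseline_rate <= 0) stop_invalid("baseline_rate must be > 0")
  if (is.null(true_shape_params)) {
    true_shape_params <- multiplier_spec(true_shape)
  }
  stopifnot(inherits(true_shape_params, "multiplier_spec"))
  structure(
    list(n_centers = as.integer(n_centers),
         physicians_per_center = as.integer(physicians_per_center),
         cases_per_physician = as.integer(cases_per_physician),
         censoring_target = censoring_target,
         true_shape = true_shape,
         true_shape_params = true_shape_params,
         beta_true = beta_true,
         theta_true = theta_true,
         center_theta = center_theta,
         baseline_rate = baseline_rate,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: %d centers x %d physicians x %d cases, %s learning, %.0f%% censoring, theta=%.2f, seed=%d\n",
    x$n_centers, x$physicians_per_center, x$cases_per_physician,
    x$true_shape, 100 * x$censoring_target, x$theta_true, x$seed))
  invisible(x)
}

## Draw the covariate block for n subjects (RNG state managed by caller).
draw_covariates <- function(n, profile) {
  out <- data.frame(age = stats::rnorm(n, profile$age_mean, profile$age_sd))
  mrs <- stats::rnorm(n, profile$mrs_mean, profile$mrs_sd)
  out$mrs <- pmin(6, pmax(0, mrs))
  for (nm in names(profile$binary_prevalences)) {
    out[[nm]] <- stats::rbinom(n, 1L, profile$binary_prevalences[[nm]])
  }
  out
}

## Linear predictor from the named true coefficients.  "age_c" and "mrs_c"
## refer to age/MRS centered at the profile means; any other name must be a
## covariate column.
true_linear_predictor <- function(covs, beta, profile) {
  lp <- numeric(nrow(covs))
  for (nm in names(beta)) {
    x <- switch(nm,
      age_c = covs$age - profile$age_mean,
      mrs_c = covs$mrs - profile$mrs_mean,
      {
        if (!nm %in% names(covs)) {
          stop_invalid("beta_true names unknown covariate '", nm, "'")
        }
        covs[[nm]]
      })
    lp <- lp + beta[[nm]] * x
  }
  lp
}

#' Calibrate an exponential censoring rate to a target proportion
#'
#' Finds, by bisection, the rate `lambda_c` of an independent exponential
#' censoring time such that the expected censoring proportion over a
#' calibration sample of uncensored event times equals `target`.  For event
#' times `T_i` the expected proportion is `mean(1 - exp(-lambda_c * T_i))`,
#' which is smooth and strictly increasing in `lambda_c`, so bisection is
#' exact up to tolerance.
#'
#' @param generate_times a closure `function(n)` returning `n` uncensored
#'   event times, or a numeric vector of event times to calibrate against.
#' @param target target censoring proportion in `(0, 1)`.
#' @param tol acceptable absolute deviation of the expected proportion.
#' @param n_calib calibration sample size (`>= 2000` recommended).
#' @return The calibrated censoring rate (events per day), with the achieved
#'   expected proportion in attribute `"expected_censoring"`.
#' @export
calibrate_censoring <- function(generate_times, target, tol = 0.005,
                                n_calib = 2000) {
  if (target <= 0 || target >= 1) stop_invalid("target must be in (0, 1)")
  times <- if (is.function(generate_times)) {
    generate_times(n_calib)
  } else {
    as.numeric(generate_times)
  }
  if (any(times <= 0)) stop_invalid("event times must be positive")
  f <- function(lam) mean(1 - exp(-lam * times)) - target

  lo <- 1e-12
  hi <- 1 / min(times)
  it <- 0
  while (f(hi) < 0 && it < 200) {
    hi <- hi * 2
    it <- it + 1
  }
  if (f(lo) > 0 || f(hi) < 0) {
    stop("censoring calibration failed to bracket the target ", target,
         " (expected censoring range ",
         signif(f(lo) + target, 3), "..", signif(f(hi) + target, 3), ")")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = tol / 100)$root
  structure(root, expected_censoring = f(root) + target)
}

#' Generate a synthetic multicenter surgical cohort
#'
#' Simulates one cohort under `config`: operators nested in centers, a
#' shared gamma frailty per operator (mean 1, variance `theta_true`),
#' covariates drawn from `profile`, and event times from the hazard
#' `baseline_rate * w_j * exp(beta' x) * g(case_order)` where `g` is the
#' true learning multiplier.  Independent exponential censoring is
#' calibrated to the configured target.  The draw is fully determined by
#' `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param profile a [covariate_profile()].
#' @return A `data.frame` (class `lc_cohort`) with one row per procedure:
#'   ids, `case_order` (within operator), `center_order` (cumulative volume
#'   within center), covariates, `time` (days) and `event` (1 = observed).
#'   The config and calibrated censoring rate are stored as attributes.
#' @export
generate_cohort <- function(config, profile = covariate_profile()) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(profile, "covariate_profile"))
  n_ops <- config$n_centers * config$physicians_per_center
  n <- n_ops * config$cases_per_physician

  with_seed(config$seed, {
    center_id <- rep(seq_len(config$n_centers),
                     each = config$physicians_per_center * config$cases_per_physician)
    operator_id <- rep(seq_len(n_ops), each = config$cases_per_physician)
    case_order <- rep(seq_len(config$cases_per_physician), times = n_ops)

    w_op <- if (config$theta_true > 0) {
      stats::rgamma(n_ops, shape = 1 / config$theta_true,
                    rate = 1 / config$theta_true)
    } else {
      rep(1, n_ops)
    }
    w_cen <- if (config$center_theta > 0) {
      stats::rgamma(config$n_centers, shape = 1 / config$center_theta,
                    rate = 1 / config$center_theta)
    } else {
      rep(1, config$n_centers)
    }

    covs <- draw_covariates(n, profile)
    lp <- true_linear_predictor(covs, config$beta_true, profile)
    g <- true_learning_multiplier(config$true_shape_params, case_order)
    haz <- config$baseline_rate * w_op[operator_id] * w_cen[center_id] *
      exp(lp) * g
    t_event <- stats::rexp(n, rate = haz)

    if (config$censoring_target > 0) {
      lam_c <- calibrate_censoring(t_event, config$censoring_target)
      t_cens <- stats::rexp(n, rate = as.numeric(lam_c))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      lam_c <- 0
      time <- t_event
      event <- rep(1L, n)
    }

    out <- data.frame(
      subject_id = seq_len(n),
      center_id = center_id,
      operator_id = operator_id,
      case_order = case_order,
      stringsAsFactors = FALSE
    )
    ## cumulative volume at the center: operators within a center work in
    ## parallel, so procedures interleave by case order (all first cases,
    ## then all second cases, ...); ties across operators break by id.
    out$center_order <- stats::ave(
      out$case_order + out$operator_id / (n_ops + 1),
      out$center_id, FUN = rank)
    out <- cbind(out, covs)
    out$time <- time
    out$event <- event
    attr(out, "config") <- config
    attr(out, "censoring_rate") <- as.numeric(lam_c)
    attr(out, "frailties") <- w_op
    class(out) <- c("lc_cohort", "data.frame")
    out
  })
}

#' Default covariate set used by the modelling layer
#' @return Character vector of cohort column names.
#' @export
default_covariates <- function() {
  c("age", "male", "diabetes", "stroke_history", "hypertension",
    "anticoagulant", "smoke", "cvd_history", "sah", "ivh", "ich",
    "mrs", "device_bactericidal")
}

#' Write / read a cohort as CSV
#'
#' Fixed, documented column order; the attributes (config, censoring rate)
#' are not serialised, only the table.
#' @param cohort an `lc_cohort` data frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "center_id", "operator_id", "case_order",
                "time", "event")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop_invalid("cohort file lacks required columns: ",
                 paste(missing, collapse = ", "))
  }
  if (!"center_order" %in% names(out)) {
    n_ops <- length(unique(out$operator_id))
    out$center_order <- stats::ave(
      out$case_order + as.integer(factor(out$operator_id)) / (n_ops + 1),
      out$center_id, FUN = rank)
  }
  class(out) <- c("lc_cohort", "data.frame")
  out
}
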