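#' Binned averages of predicted success probabilities by volume
#'
#' Half-open volume bins `[1, 1+w), [1+w, 1+2w), ...`; each point is the
#' mean probability of the cases falling in the bin.  Empty bins are
#' omitted.  Bin centers are `lower + (w - 1) / 2`, so width-1 binning
#' returns the raw per-volume means at the volumes themselves.
#'
#' @param volumes case volumes (`>= 1`).
#' @param probabilities probabilities aligned with `volumes`.
#' @param width bin width (`>= 1`).
#' @return Data frame with `center`, `mean` and `n` per non-empty bin.
#' @export
bin_observed <- function(volumes, probabilities, width = 5) {
  stopifnot(length(volumes) == length(probabilities))
  if (width < 1) stop("bin width must be >= 1")
  if (length(volumes) == 0) {
    return(data.frame(center = numeric(0), mean = numeric(0),
                      n = integer(0)))
  }
  idx <- floor((volumes - 1) / width)
  agg <- tapply(probabilities, idx, mean)
  cnt <- tapply(probabilities, idx, length)
  k <- as.numeric(names(agg))
  data.frame(center = 1 + k * width + (width - 1) / 2,
             mean = as.numeric(agg), n = as.integer(cnt))
}

#' Learning-curve mean-squared-error family
#'
#' Four complementary discrepancies: `mse1` between the binned observed
#' means and the fitted curve at the bin centers; `mse2` between the
#' steady-state probabilities `p0` and the final fitted shape values;
#' `mse2_a` between `p0` and the physician-level predictions `p1`;
#' `mse2_b` between `p1` and the center-level predictions `p2`.
#'
#' @param binned_observed binned observed means.
#' @param fitted_curve fitted shape values at the same bin centers.
#' @param p0,p1,p2 per-subject probability vectors (aligned).
#' @param shape_values final fitted shape evaluated at the subjects' case
#'   orders (aligned with `p0`).
#' @return An object of class `mse_report`.
#' @export
mse_report <- function(binned_observed, fitted_curve, p0, p1, p2,
                       shape_values) {
  structure(
    list(mse1 = mse(binned_observed, fitted_curve),
         mse2 = mse(p0, shape_values),
         mse2_a = mse(p0, p1),
         mse2_b = mse(p1, p2)),
    class = "mse_report"
  )
}

#' @export
print.mse_report <- function(x, ...) {
  cat(sprintf("MSE1 %.4f | MSE2 %.4f | MSE2_a %.4f | MSE2_b %.4f\n",
              x$mse1, x$mse2, x$mse2_a, x$mse2_b))
  invisible(x)
}

#' Learning-adjusted survival-time update
#'
#' `tnew_i = (p2_i / p0_i) * time_i`: the observed time rescaled by the
#' ratio of the final (center-level) success probability to the
#' steady-state probability.  Wherever `p2 = p0` the time is unchanged.
#'
#' @param p0 steady-state probabilities (`> 0`).
#' @param p2 final center-level probabilities.
#' @param time observed survival times.
#' @return Updated survival times.
#' @export
update_times <- function(p0, p2, time) {
  stopifnot(length(p0) == length(p2), length(p0) == length(time))
  if (any(p0 <= 0)) stop("p0 must be strictly positive")
  (p2 / p0) * time
}

## One backend fit + prediction at horizon for every cohort row.
backend_predict <- function(cohort, covariates, backend, horizon,
                            rsf_cfg, tau) {
  switch(backend,
    cox = {
      fit <- fit_cox(cohort, covariates, cluster = "operator_id")
      suppressWarnings(predict_survival(fit, cohort, horizon))
    },
    frailty = {
      fit <- fit_frailty(cohort, covariates, cluster = "operator_id")
      suppressWarnings(predict_survival(fit, cohort, horizon))
    },
    rmst_frailty = {
      fit <- fit_rmst_frailty_regression(cohort, covariates,
                                         cluster = "operator_id",
                                         tau = tau)
      suppressWarnings(predict_survival(fit, cohort, min(horizon, tau)))
    },
    rsf = rsf_predict(cohort, covariates, rsf_cfg, horizon),
    stop("unknown backend '", backend, "'")
  )
}

#' Supported learning-curve backends
#' @return Character vector of backend names.
#' @export
lc_backends <- function() c("cox", "frailty", "rmst_frailty", "rsf")

#' Run the multilevel learning-curve pipeline
#'
#' Implements the full learning-curve construction on one cohort:
#' \enumerate{
#'   \item `p0`: predicted survival at `horizon` from the backend fit
#'     \emph{without} the ordered procedure variable — the asymptotic
#'     steady-state success probability per subject.
#'   \item Physician level: the backend is refit \emph{with} the ordered
#'     procedure variable; the chosen shape is fit to those predictions
#'     against operator case order, giving smoothed probabilities `p1`.
#'   \item Center level: the same shape family is refit against cumulative
#'     center volume with `p1` as input, giving final probabilities `p2`.
#'   \item Update rule: `tnew = (p2 / p0) * time` (see [update_times()]).
#'   \item One refit pass on the updated times produces the new success
#'     probabilities and the final fitted shape.  The MSE family (see
#'     [mse_report()]) compares that curve with the binned \emph{marginal
#'     observed success rates} (event-free at the horizon), and the
#'     probability levels with each other.
#' }
#'
#' @param cohort an `lc_cohort` data frame (needs `case_order` and
#'   `center_order` columns).
#' @param backend one of [lc_backends()].
#' @param kind learning-curve shape family, see [shape_kinds()].
#' @param horizon survival-evaluation horizon in days (default 30).
#' @param bin_width volume bin width for the observed points (default 5).
#' @param covariates adjustment covariates (default [default_covariates()]).
#' @param rsf_cfg an [rsf_config()] for the `rsf` backend.
#' @param tau restriction horizon for the `rmst_frailty` backend; defaults
#'   to the 75th percentile of observed follow-up.
#' @return An object of class `lc_result`: `p0`, `p1`, `p2`, `tnew`,
#'   `updated` (post-update predictions), `shape_fit` (physician, center
#'   and final fits), `binned` (binned predictions, for plotting),
#'   `observed` (binned marginal success rates), `fitted` (curve at bin
#'   centers), and `mse`.
#' @export
run_lc_pipeline <- function(cohort, backend = lc_backends(),
                            kind = shape_kinds(), horizon = 30,
                            bin_width = 5,
                            covariates = default_covariates(),
                            rsf_cfg = rsf_config(), tau = NULL) {
  backend <- match.arg(backend)
  kind <- match.arg(kind)
  d <- as.data.frame(cohort)
  stopifnot(all(c("case_order", "center_order", "time", "event") %in% names(d)))
  if (horizon > max(d$time)) stop("horizon beyond follow-up")
  tau <- tau %||% as.numeric(stats::quantile(d$time, 0.75))

  ord <- d$case_order
  cvol <- d$center_order
  covs_ord <- c(covariates, "case_order")

  p0 <- backend_predict(d, covariates, backend, horizon, rsf_cfg, tau)
  q1 <- backend_predict(d, covs_ord, backend, horizon, rsf_cfg, tau)

  f1 <- fit_shape(ord, q1, kind)
  p1 <- shape_value(f1$spec, ord)
  f2 <- fit_shape(cvol, p1, kind)
  p2 <- shape_value(f2$spec, cvol)

  eps <- 1e-6
  p0c <- pmax(p0, eps)
  p2c <- pmax(p2, eps)
  tnew <- update_times(p0c, p2c, d$time)

  d2 <- d
  d2$time <- tnew
  tau2 <- as.numeric(stats::quantile(d2$time, 0.75))
  updated <- backend_predict(d2, covs_ord, backend,
                             min(horizon, max(d2$time)), rsf_cfg, tau2)
  f3 <- fit_shape(ord, updated, kind)
  svals <- shape_value(f3$spec, ord)
  binned <- bin_observed(ord, updated, bin_width)
  ## marginal observed success: still event-free at the horizon (censored
  ## earlier counts as failure, so heavy censoring degrades the agreement)
  observed <- bin_observed(ord, as.numeric(d$time > horizon), bin_width)
  fitted_at <- shape_value(f3$spec, observed$center)

  structure(
    list(p0 = p0, p1 = p1, p2 = p2, tnew = tnew, updated = updated,
         orders = ord, center_orders = cvol,
         shape_fit = list(physician = f1, center = f2, final = f3),
         binned = binned, observed = observed, fitted = fitted_at,
         mse = mse_report(observed$mean, fitted_at, p0, p1, p2, svals),
         backend = backend, kind = kind, horizon = horizon,
         bin_width = bin_width),
    class = "lc_result"
  )
}

#' @export
print.lc_result <- function(x, ...) {
  cat(sprintf("Learning-curve result: backend %s, shape %s, horizon %g d\n",
              x$backend, x$kind, x$horizon))
  cat(sprintf("  mean p0 %.3f | mean p1 %.3f | mean p2 %.3f | %d bins\n",
              mean(x$p0), mean(x$p1), mean(x$p2), nrow(x$binned)))
  print(x$mse)
  invisible(x)
}
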