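#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' The RMST at horizon `tau` is the area under the survival curve on
#' `[0, tau]`, computed as the exact integral of the Kaplan-Meier step
#' function.  The standard error uses the Greenwood-type variance
#' `sum_k A_k^2 d_k / (n_k (n_k - d_k))`, `A_k` the area from event time
#' `t_k` to `tau`.
#'
#' @param curve a `survival_curve` from [km_estimate()].
#' @param tau horizon in days; must not exceed the last observed time.
#' @return An object of class `rmst_result`: list with `tau`, `estimate`
#'   (days), `se`.
#' @export
rmst_km <- function(curve, tau) {
  stopifnot(inherits(curve, "survival_curve"))
  if (tau <= 0) stop("tau must be positive")
  if (tau > max(curve$time)) {
    stop("horizon error: tau = ", tau, " exceeds last observed time ",
         max(curve$time))
  }
  est <- integrate_step(curve$time, curve$surv, tau)
  ## curves without risk-set bookkeeping (e.g. model baselines) get no se
  if (all(is.na(curve$n_event))) {
    return(structure(list(tau = tau, estimate = est, se = NA_real_,
                          group = NULL), class = "rmst_result"))
  }
  ev <- which(!is.na(curve$n_event) & curve$n_event > 0 & curve$time < tau)
  v <- 0
  for (k in ev) {
    A <- integrate_step(curve$time, curve$surv, tau) -
      integrate_step(curve$time, curve$surv, curve$time[k])
    nk <- curve$n_risk[k]
    dk <- curve$n_event[k]
    if (nk - dk > 0) v <- v + A^2 * dk / (nk * (nk - dk))
  }
  structure(list(tau = tau, estimate = est, se = sqrt(v), group = NULL),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("RMST(tau = %g) = %.4f days (se %.4f)\n",
              x$tau, x$estimate, x$se))
  invisible(x)
}

#' RMST from a frailty-model baseline
#'
#' Integrates the covariate-adjusted survival
#' `S0(u) ^ (w * exp(beta' x))` over `[0, tau]`, averaged over the fitted
#' cluster frailties (population-averaged survival).  For a plain Cox fit
#' the frailty set is `{1}`.
#'
#' @param fit a `cox_fit` or `frailty_fit`.
#' @param covariates named covariate vector for the subject profile
#'   (defaults to all zero, i.e. the baseline profile).
#' @param tau horizon in days, within the baseline support.
#' @param stratum stratum label for stratified fits.
#' @return An `rmst_result` (no analytic `se`; see [rmst_difference()] for
#'   bootstrap intervals).
#' @export
rmst_frailty <- function(fit, tau, covariates = NULL, stratum = NULL) {
  base <- get_baseline(fit, stratum)
  if (tau <= 0) stop("tau must be positive")
  if (nrow(base) == 0) {
    return(structure(list(tau = tau, estimate = tau, se = NA_real_,
                          group = NULL), class = "rmst_result"))
  }
  if (tau > max(base$time)) {
    stop("horizon error: tau = ", tau, " beyond baseline support ",
         max(base$time))
  }
  eta <- 0
  if (!is.null(covariates)) {
    nm <- intersect(names(covariates), names(fit$beta))
    eta <- sum(fit$beta[nm] * covariates[nm])
  }
  w <- fit$frailties %||% 1
  est <- mean(vapply(w, function(wj) {
    integrate_step(base$time, exp(-base$cumhaz * wj * exp(eta)), tau)
  }, numeric(1)))
  structure(list(tau = tau, estimate = est, se = NA_real_, group = NULL),
            class = "rmst_result")
}

#' RMST difference between two groups with a cluster bootstrap CI
#'
#' Point estimate: difference of the groups' Kaplan-Meier RMSTs (first
#' factor level minus second).  Confidence interval: percentile interval
#' from a cluster bootstrap that resamples operators with replacement,
#' preserving within-operator correlation.
#'
#' @param cohort cohort data frame with `time`, `event`, the group column,
#'   and the cluster column.
#' @param group column name of a two-level grouping variable.
#' @param tau horizon, within both groups' follow-up.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param cluster column resampled by the bootstrap (default
#'   `"operator_id"`).
#' @param conf confidence level.
#' @return List with `estimate`, `ci` (length 2), `tau` and the bootstrap
#'   replicates `boot`.
#' @export
rmst_difference <- function(cohort, group, tau, n_boot = 500, seed = 1,
                            cluster = "operator_id", conf = 0.95) {
  d <- as.data.frame(cohort)
  g <- as.factor(d[[group]])
  if (nlevels(droplevels(g)) != 2) stop("group must have exactly two levels")
  lv <- levels(droplevels(g))
  diff_fn <- function(dd, gg) {
    r <- vapply(lv, function(l) {
      idx <- gg == l
      if (!any(dd$event[idx] == 1)) {
        warning("group '", l, "' has no events before tau")
      }
      rmst_km(km_estimate(dd$time[idx], dd$event[idx]), tau)$estimate
    }, numeric(1))
    unname(r[1] - r[2])
  }
  est <- diff_fn(d, g)
  cl <- d[[cluster]]
  ids <- unique(cl)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(lapply(take, function(i) which(cl == i)))
    dd <- d[rows, , drop = FALSE]
    tryCatch(suppressWarnings(diff_fn(dd, as.factor(dd[[group]]))),
             error = function(e) NA_real_)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(estimate = est, ci = ci, tau = tau, boot = boot)
}

#' RMST-frailty regression via horizon truncation
#'
#' Refits the shared gamma-frailty Cox model on tau-restricted data: events
#' after `tau` are recoded as censored at `tau` and all follow-up is capped
#' at `tau`, so the coefficients describe covariate effects on the
#' tau-restricted survival experience.
#'
#' @param cohort cohort data frame.
#' @param covariates covariate column names.
#' @param cluster frailty grouping column.
#' @param tau restriction horizon (days).
#' @param ... passed to [fit_frailty()].
#' @return A `frailty_fit` (additionally classed `rmst_frailty_fit`) with
#'   attribute `"tau"`.
#' @export
fit_rmst_frailty_regression <- function(cohort, covariates, cluster, tau,
                                        ...) {
  if (tau <= 0) stop("tau must be positive")
  d <- as.data.frame(cohort)
  d$event <- ifelse(d$time > tau, 0L, d$event)
  d$time <- pmin(d$time, tau)
  if (sum(d$event) < 1) {
    stop("tau = ", tau, " leaves no events; choose a larger horizon")
  }
  fit <- fit_frailty(d, covariates, cluster, ...)
  attr(fit, "tau") <- tau
  class(fit) <- c("rmst_frailty_fit", class(fit))
  fit
}
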