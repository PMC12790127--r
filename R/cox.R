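## Design-matrix assembly shared by the Cox and frailty fitters.
build_design <- function(cohort, covariates) {
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols)) {
    stop_invalid("cohort lacks covariate columns: ",
                 paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(cohort)[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  const <- apply(X, 2, function(v) max(v) - min(v) < .Machine$double.eps * 100)
  if (any(const)) {
    stop("constant covariate(s): ", paste(covariates[const], collapse = ", "))
  }
  X
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' Increments `d_k / sum(exp(lp))` over the risk set at each distinct event
#' time, computed within stratum.  `lp` is the full linear predictor
#' (covariates plus any log-frailty offset).
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param lp linear predictor per subject.
#' @param strata optional stratum labels.
#' @return A named list (one element per stratum, `"all"` when unstratified)
#'   of data frames with columns `time`, `haz` (increment) and `cumhaz`.
#' @export
breslow_cumhaz <- function(time, event, lp, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", length(time))
  strata <- as.character(strata)
  out <- list()
  for (s in unique(strata)) {
    idx <- strata == s
    tt <- time[idx]; ee <- event[idx]; ss <- exp(lp[idx])
    et <- sort(unique(tt[ee == 1]))
    if (length(et) == 0) {
      out[[s]] <- data.frame(time = numeric(0), haz = numeric(0),
                             cumhaz = numeric(0))
      next
    }
    haz <- vapply(et, function(t0) {
      sum(ee[tt == t0]) / sum(ss[tt >= t0])
    }, numeric(1))
    out[[s]] <- data.frame(time = et, haz = haz, cumhaz = cumsum(haz))
  }
  out
}

## Evaluate a per-stratum cumulative hazard at times t (right-continuous).
eval_cumhaz <- function(base, t) {
  vapply(t, function(tt) {
    k <- findInterval(tt, base$time)
    if (k == 0) 0 else base$cumhaz[k]
  }, numeric(1))
}

#' Cox proportional hazards fit with cluster-robust variance
#'
#' Wraps [survival::coxph()] (Efron ties) with an optional grouped sandwich
#' variance (clustering by operator is the usual choice for multicenter
#' surgical data) and attaches a per-stratum Breslow baseline.
#'
#' @param cohort cohort data frame with `time` and `event` columns.
#' @param covariates covariate column names.
#' @param cluster optional column name for the robust-variance grouping.
#' @param strata optional column name defining baseline strata.
#' @param offset optional per-subject offset on the log-hazard scale.
#' @return An object of class `cox_fit` with elements `beta`, `se_naive`,
#'   `se_robust`, `loglik`, `baseline`, and bookkeeping fields.
#' @export
fit_cox <- function(cohort, covariates, cluster = NULL, strata = NULL,
                    offset = NULL) {
  d <- as.data.frame(cohort)
  if (sum(d$event) < 1) stop("need at least one event")
  X <- build_design(d, covariates)
  off <- offset %||% rep(0, nrow(d))

  strat <- if (!is.null(strata)) as.factor(d[[strata]]) else NULL
  sdata <- data.frame(.time = d$time, .event = d$event, .off = off)
  sdata <- cbind(sdata, as.data.frame(X))
  rhs <- paste(c(sprintf("`%s`", covariates), "offset(.off)"), collapse = " + ")
  if (!is.null(strat)) {
    sdata$.strat <- strat
    rhs <- paste(rhs, "+ strata(.strat)")
  }
  if (!is.null(cluster)) sdata$.cl <- as.factor(d[[cluster]])
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))

  fit <- if (!is.null(cluster)) {
    survival::coxph(fml, data = sdata, ties = "efron", cluster = .cl)
  } else {
    survival::coxph(fml, data = sdata, ties = "efron")
  }
  beta <- stats::coef(fit)
  if (any(is.na(beta))) {
    stop("singular design: coefficients not estimable for ",
         paste(covariates[is.na(beta)], collapse = ", "))
  }
  names(beta) <- covariates
  ## with a cluster term coxph stores the sandwich in $var and the
  ## model-based variance in $naive.var
  if (!is.null(cluster)) {
    se_naive <- sqrt(diag(fit$naive.var))
    se_robust <- sqrt(diag(fit$var))
  } else {
    se_naive <- sqrt(diag(fit$var))
    se_robust <- se_naive
  }
  lp <- as.numeric(X %*% beta) + off
  baseline <- breslow_cumhaz(d$time, d$event, lp,
                             if (!is.null(strat)) strat else NULL)
  structure(
    list(beta = beta, se_naive = se_naive, se_robust = se_robust,
         loglik = fit$loglik[length(fit$loglik)],
         covariates = covariates, cluster_var = cluster,
         strata_var = strata, baseline = baseline,
         theta = 0, frailties = NULL, model = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model (Efron ties), ", length(x$beta), " covariates",
      if (!is.null(x$cluster_var)) paste0(", cluster-robust by ", x$cluster_var),
      "\n", sep = "")
  hr <- exp(x$beta)
  print(data.frame(coef = round(x$beta, 4), HR = round(hr, 4),
                   se = round(x$se_naive, 4),
                   robust_se = round(x$se_robust, 4)))
  invisible(x)
}

#' Baseline survival curve of a fitted model
#'
#' `S0(t) = exp(-Lambda0(t))` with the Breslow cumulative hazard of the
#' requested stratum; frailty fits include the log-frailty offsets in the
#' risk-set weights.
#'
#' @param fit a `cox_fit` or `frailty_fit`.
#' @param stratum stratum label (ignored for unstratified fits).
#' @return A `survival_curve`.
#' @export
baseline_survival <- function(fit, stratum = NULL) {
  base <- get_baseline(fit, stratum)
  structure(
    list(time = base$time, surv = exp(-base$cumhaz),
         n_risk = rep(NA_integer_, nrow(base)),
         n_event = rep(NA_integer_, nrow(base))),
    class = "survival_curve"
  )
}

get_baseline <- function(fit, stratum = NULL) {
  if (is.null(stratum)) {
    if (length(fit$baseline) > 1) {
      stop("fit is stratified; supply a stratum")
    }
    fit$baseline[[1]]
  } else {
    s <- as.character(stratum)
    if (!s %in% names(fit$baseline)) stop("unknown stratum '", s, "'")
    fit$baseline[[s]]
  }
}

#' Predicted survival probability for a subject
#'
#' `S0(t) ^ exp(beta' x + log w)`, where `w` is the subject's operator
#' frailty for frailty fits (1 otherwise, or when the operator was not seen
#' at fit time).
#'
#' @param fit a `cox_fit` or `frailty_fit`.
#' @param newdata data frame of subjects (must contain the fit's covariates;
#'   a cluster id column enables frailty lookup).
#' @param horizon evaluation time `t >= 0` (days).
#' @param stratum stratum label for stratified fits.
#' @return Probabilities in `[0, 1]`, one per row of `newdata`.
#' @export
predict_survival <- function(fit, newdata, horizon, stratum = NULL) {
  stopifnot(horizon >= 0)
  base <- get_baseline(fit, stratum)
  if (nrow(base) == 0) return(rep(1, nrow(newdata)))
  if (horizon > max(base$time)) {
    warning("horizon ", horizon, " beyond baseline support; using value at ",
            max(base$time))
    horizon <- max(base$time)
  }
  ch0 <- eval_cumhaz(base, horizon)
  X <- as.matrix(as.data.frame(newdata)[, fit$covariates, drop = FALSE])
  storage.mode(X) <- "double"
  lp <- as.numeric(X %*% fit$beta)
  logw <- rep(0, nrow(X))
  if (!is.null(fit$frailties) && !is.null(fit$cluster_var) &&
      fit$cluster_var %in% names(newdata)) {
    cl <- as.character(newdata[[fit$cluster_var]])
    hit <- cl %in% names(fit$frailties)
    logw[hit] <- log(fit$frailties[cl[hit]])
  }
  exp(-ch0 * exp(lp + logw))
}
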