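#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return An object of class `survival_curve`: a list with `time`
#'   (ordered unique observed times), `surv` (step-function values),
#'   `n_risk` and `n_event` per time.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival step function on", length(x$time), "time points; final S =",
      signif(x$surv[length(x$surv)], 4), "\n")
  invisible(x)
}

## Evaluate a survival_curve (right-continuous step, S(0)=1) at times t.
eval_curve <- function(curve, t) {
  vapply(t, function(tt) {
    k <- findInterval(tt, curve$time)
    if (k == 0) 1 else curve$surv[k]
  }, numeric(1))
}

#' Log-rank test for equality of survival curves
#'
#' @param groups group labels (two or more groups).
#' @param times positive follow-up times.
#' @param events event indicators.
#' @return A list with `statistic` (chi-squared), `df` and `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("log-rank test needs at least two groups")
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(statistic = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}
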