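#' Export results as deterministic CSV tables
#'
#' Fixed column orders and explicit `NA` tokens so reruns of the same
#' result are byte-identical.  Layouts: `"table6"` (the 16-row scenario
#' grid), `"table7"` (per-scenario per-backend MSEs), `"table8"`
#' (hazard-scale level summaries), and `"model_summary"` (one row per
#' coefficient of a Cox or frailty fit).
#'
#' @param result a `study_result` (tables 6-8) or `cox_fit`/`frailty_fit`
#'   (`model_summary`).
#' @param layout one of `"table6"`, `"table7"`, `"table8"`,
#'   `"model_summary"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, layout = c("table6", "table7", "table8",
                                           "model_summary"), path) {
  layout <- match.arg(layout)
  tab <- switch(layout,
    table6 = {
      stopifnot(inherits(result, "study_result"))
      result$grid
    },
    table7 = {
      stopifnot(inherits(result, "study_result"))
      result$mse_table
    },
    table8 = {
      stopifnot(inherits(result, "study_result"))
      result$level_table
    },
    model_summary = model_summary_table(result)
  )
  utils::write.csv(tab, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Coefficient table of a fitted model
#'
#' @param fit a `cox_fit` or `frailty_fit`.
#' @param conf confidence level for the hazard-ratio interval.
#' @return Data frame with columns `term`, `coef`, `se`, `robust_se`, `HR`,
#'   `ci_low`, `ci_high`, `p`; frailty fits append a row for the frailty
#'   variance and its boundary-LRT p-value.
#' @export
model_summary_table <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- fit$se_robust %||% fit$se_naive
  tab <- data.frame(
    term = names(fit$beta),
    coef = as.numeric(fit$beta),
    se = as.numeric(fit$se_naive),
    robust_se = as.numeric(se),
    HR = exp(as.numeric(fit$beta)),
    ci_low = exp(as.numeric(fit$beta) - z * se),
    ci_high = exp(as.numeric(fit$beta) + z * se),
    p = 2 * stats::pnorm(-abs(as.numeric(fit$beta) / se)),
    stringsAsFactors = FALSE
  )
  if (inherits(fit, "frailty_fit")) {
    tab <- rbind(tab, data.frame(
      term = "frailty_variance", coef = fit$theta, se = NA_real_,
      robust_se = NA_real_, HR = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p = fit$frailty_pvalue,
      stringsAsFactors = FALSE
    ))
  }
  tab
}

#' Export learning-curve plot data
#'
#' Long-format CSV with one row per (volume bin center, series) pair;
#' series are the binned `observed` means, the `fitted` shape values at
#' the bin centers, and the binned means of `p0`, `p1` and `p2`.  Enough
#' to redraw the standard learning-curve panels with any plotting layer.
#'
#' @param lc an `lc_result` from [run_lc_pipeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
plot_lc_data <- function(lc, path) {
  stopifnot(inherits(lc, "lc_result"))
  centers <- lc$binned$center
  rows <- rbind(
    data.frame(volume = centers, series = "observed", value = lc$binned$mean),
    data.frame(volume = centers, series = "fitted", value = lc$fitted)
  )
  for (s in c("p0", "p1", "p2")) {
    b <- bin_observed(lc$orders, lc[[s]], lc$bin_width)
    rows <- rbind(rows, data.frame(volume = b$center, series = s,
                                   value = b$mean))
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
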