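#' Random survival forest configuration
#'
#' Hyperparameters for the random-survival-forest backend (delegated to
#' \pkg{ranger}); recorded alongside predictions for reproducibility.
#'
#' @param n_trees number of trees (default 500).
#' @param min_node_size minimal terminal node size (`NULL` = ranger's
#'   survival default).
#' @param mtry covariates tried per split (`NULL` = default `sqrt(p)`).
#' @param seed integer seed fixing the forest.
#' @return An object of class `rsf_config`.
#' @export
rsf_config <- function(n_trees = 500, min_node_size = NULL, mtry = NULL,
                       seed = 1L) {
  if (n_trees < 1) stop_invalid("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = min_node_size, mtry = mtry,
                 seed = as.integer(seed)),
            class = "rsf_config")
}

#' Out-of-bag survival predictions from a random survival forest
#'
#' Grows a survival forest on the cohort and returns each subject's
#' out-of-bag ensemble survival probability at `horizon` (the OOB survival
#' step function evaluated at the last death time at or before `horizon`).
#' Deterministic given `config$seed`; single-threaded for reproducibility.
#'
#' @param cohort cohort data frame with `time` and `event`.
#' @param covariates covariate column names used as features.
#' @param config an [rsf_config()].
#' @param horizon evaluation time (days), within follow-up.
#' @return Probabilities in `[0, 1]`, one per subject.
#' @export
rsf_predict <- function(cohort, covariates, config = rsf_config(),
                        horizon) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("random survival forest backend unavailable: package 'ranger' ",
         "is not installed")
  }
  d <- as.data.frame(cohort)
  if (sum(d$event) < 1) stop("need at least one event")
  stopifnot(horizon >= 0)
  if (horizon > max(d$time)) {
    warning("horizon beyond follow-up; using last observed time")
    horizon <- max(d$time)
  }
  feat <- d[, covariates, drop = FALSE]
  feat$.time <- d$time
  feat$.event <- d$event
  args <- list(
    formula = stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", covariates), collapse = " + "))),
    data = feat,
    num.trees = config$n_trees,
    num.threads = 1,
    seed = config$seed,
    oob.error = TRUE
  )
  if (!is.null(config$min_node_size)) args$min.node.size <- config$min_node_size
  if (!is.null(config$mtry)) args$mtry <- config$mtry
  rf <- do.call(ranger::ranger, args)
  tt <- rf$unique.death.times
  k <- findInterval(horizon, tt)
  p <- if (k == 0) rep(1, nrow(d)) else rf$survival[, k]
  clamp01(as.numeric(p))
}
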