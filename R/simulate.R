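#' The 16-scenario factorial grid
#'
#' Full cross of physicians per center (10, 5), censoring (10%, 70%) and
#' true learning shape (exponential, power series, logarithmic,
#' log-normal), numbered 1-16: scenarios 1-4 are 10 physicians / 10%
#' censoring across the four shapes, 5-8 are 5 / 10%, 9-12 are 10 / 70%,
#' and 13-16 are 5 / 70%.
#'
#' @param ... overrides passed to every [scenario_config()] (e.g.
#'   `theta_true`, `cases_per_physician`).
#' @return A list of 16 `scenario_config` objects; each carries its
#'   scenario number in attribute `"scenario"`.
#' @export
scenario_grid <- function(...) {
  blocks <- list(c(10, 0.10), c(5, 0.10), c(10, 0.70), c(5, 0.70))
  shapes <- shape_kinds()
  out <- vector("list", 16L)
  i <- 0L
  for (b in blocks) {
    for (sh in shapes) {
      i <- i + 1L
      cfg <- scenario_config(physicians_per_center = b[1],
                             censoring_target = b[2],
                             true_shape = sh, ...)
      attr(cfg, "scenario") <- i
      out[[i]] <- cfg
    }
  }
  names(out) <- paste0("s", seq_len(16L))
  out
}

#' Deterministic per-replicate seed derivation
#'
#' Counter scheme mixing the master seed, scenario number and replicate
#' index into a 32-bit-safe integer, so replicate streams are reproducible
#' and distinct.
#'
#' @param master master seed (integer).
#' @param scenario scenario number.
#' @param rep replicate index.
#' @return Integer seed below `2^31`.
#' @export
replicate_seed <- function(master, scenario, rep) {
  as.integer((abs(as.numeric(master)) * 69069 + scenario * 10007 + rep) %%
               2147483647)
}

#' Default replicate counts per backend
#'
#' 50 replicates per scenario for the Cox, frailty Cox and random survival
#' forest backends; 10 for the RMST frailty backend, whose repeated
#' truncate-and-refit cycles are the most expensive step.
#' @return Named integer vector.
#' @export
default_n_reps <- function() {
  c(cox = 50L, frailty = 50L, rsf = 50L, rmst_frailty = 10L)
}

## Marginal-KM-referenced hazard-scale summary of one probability level:
## the mean, over subjects, of -log(p_i) / -log(S_KM(horizon)), i.e. the
## cumulative-hazard ratio of the level's predictions to the marginal
## Kaplan-Meier survival at the horizon.
hazard_level_summary <- function(p, km_p) {
  eps <- 1e-12
  mean(log(pmax(p, eps)) / log(max(min(km_p, 1 - eps), eps)))
}

#' Run all replicates of one simulation scenario
#'
#' Per replicate: generate a cohort under `config` with a seed derived from
#' the master seed, run the learning-curve pipeline for every requested
#' backend with the scenario's true shape, and collect the MSE family plus
#' hazard-scale level summaries.  Non-converged replicates are excluded and
#' counted, never imputed.
#'
#' @param config a [scenario_config()]; its `true_shape` is also the fitted
#'   shape family.
#' @param backends subset of [lc_backends()].
#' @param n_reps named replicate counts per backend (see
#'   [default_n_reps()]); a single number recycles to every backend.
#' @param seed master seed.
#' @param horizon,bin_width passed to [run_lc_pipeline()].
#' @return An object of class `scenario_result`: per-backend mean MSEs,
#'   level summaries (per-subject pooled means and per-replicate means),
#'   replicate counts and failure counts.
#' @export
run_scenario <- function(config, backends = c("cox", "frailty"),
                         n_reps = default_n_reps(), seed = 1,
                         horizon = 30, bin_width = 5) {
  stopifnot(inherits(config, "scenario_config"))
  backends <- match.arg(backends, lc_backends(), several.ok = TRUE)
  if (length(n_reps) == 1 && is.null(names(n_reps))) {
    n_reps <- stats::setNames(rep(as.integer(n_reps), length(backends)),
                              backends)
  }
  if (any(n_reps < 1)) stop_invalid("n_reps must be >= 1")
  scen <- attr(config, "scenario") %||% 0L
  max_reps <- max(n_reps[backends])

  rows <- list()
  failures <- stats::setNames(integer(length(backends)), backends)
  for (r in seq_len(max_reps)) {
    cfg <- config
    cfg$seed <- replicate_seed(seed, scen, r)
    cohort <- generate_cohort(cfg)
    kmp <- eval_curve(km_estimate(cohort$time, cohort$event), horizon)
    for (b in backends) {
      if (r > n_reps[[b]]) next
      res <- tryCatch(
        run_lc_pipeline(cohort, backend = b, kind = config$true_shape,
                        horizon = horizon, bin_width = bin_width),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[b]] <- failures[[b]] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        backend = b, rep = r,
        mse1 = res$mse$mse1, mse2 = res$mse$mse2,
        mse2_a = res$mse$mse2_a, mse2_b = res$mse$mse2_b,
        hr_p0 = hazard_level_summary(res$p0, kmp),
        hr_p1 = hazard_level_summary(res$p1, kmp),
        hr_p2 = hazard_level_summary(res$p2, kmp),
        stringsAsFactors = FALSE
      )
    }
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps)) stop("all replicates failed for scenario ", scen)
  agg <- do.call(rbind, lapply(split(reps, reps$backend), function(g) {
    data.frame(backend = g$backend[1], n_reps = nrow(g),
               t(colMeans(g[, c("mse1", "mse2", "mse2_a", "mse2_b",
                                "hr_p0", "hr_p1", "hr_p2")])),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(
    list(scenario = scen, config = config, summary = agg,
         replicates = reps, failures = failures, seed = seed),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$scenario, "-", x$config$true_shape, "shape,",
      sprintf("%d physicians/center, %.0f%% censoring\n",
              x$config$physicians_per_center,
              100 * x$config$censoring_target))
  print(x$summary, digits = 4)
  if (any(x$failures > 0)) {
    cat("failures:", paste(names(x$failures), x$failures, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Run the full factorial simulation study
#'
#' Runs [run_scenario()] over a scenario grid and assembles the three study
#' tables: the scenario grid itself, the per-scenario per-backend MSE table
#' and the hazard-scale level-summary table.  Missing cells (failed or
#' unrequested backend/scenario combinations) carry explicit `NA`.
#'
#' @param configs scenario list from [scenario_grid()] (or a subset).
#' @param backends subset of [lc_backends()].
#' @param n_reps named replicate counts (see [default_n_reps()]).
#' @param seed master seed.
#' @param out_dir optional directory; when given, `table6_grid.csv`,
#'   `table7_mse.csv`, `table8_levels.csv` and `metadata.json` are written.
#' @param ... passed to [run_scenario()].
#' @return An object of class `study_result` with elements `scenarios`
#'   (list of `scenario_result`), `grid`, `mse_table`, `level_table`,
#'   `metadata`.
#' @export
run_study <- function(configs = scenario_grid(),
                      backends = c("cox", "frailty"),
                      n_reps = default_n_reps(), seed = 1,
                      out_dir = NULL, ...) {
  if (length(backends) < 1) stop_invalid("need at least one backend")
  results <- lapply(configs, function(cfg) {
    run_scenario(cfg, backends = backends, n_reps = n_reps, seed = seed,
                 ...)
  })

  grid <- do.call(rbind, lapply(configs, function(cfg) {
    data.frame(scenario = attr(cfg, "scenario"),
               physicians_per_center = cfg$physicians_per_center,
               censoring = sprintf("%.0f%%", 100 * cfg$censoring_target),
               shape = cfg$true_shape, stringsAsFactors = FALSE)
  }))
  rownames(grid) <- NULL

  cell <- function(res, b, col) {
    s <- res$summary
    v <- s[s$backend == b, col]
    if (length(v) == 0) NA_real_ else v
  }
  mse_table <- do.call(rbind, lapply(results, function(res) {
    row <- data.frame(scenario = res$scenario)
    for (b in backends) {
      for (m in c("mse1", "mse2", "mse2_a", "mse2_b")) {
        row[[paste(b, m, sep = "_")]] <- cell(res, b, m)
      }
    }
    row
  }))
  rownames(mse_table) <- NULL

  level_table <- do.call(rbind, lapply(results, function(res) {
    row <- data.frame(scenario = res$scenario)
    for (b in backends) {
      for (m in c("hr_p0", "hr_p1", "hr_p2")) {
        row[[paste(b, m, sep = "_")]] <- cell(res, b, m)
        reps <- res$replicates
        v <- reps[reps$backend == b, m]
        row[[paste(b, m, "rep_mean", sep = "_")]] <-
          if (length(v)) mean(v) else NA_real_
      }
    }
    row
  }))
  rownames(level_table) <- NULL

  metadata <- list(
    package_version = as.character(utils::packageVersion("survlc")),
    master_seed = seed,
    backends = backends,
    n_reps = as.list(n_reps),
    scenarios = lapply(configs, function(cfg) {
      c(scenario = attr(cfg, "scenario"),
        unclass(cfg)[c("n_centers", "physicians_per_center",
                       "cases_per_physician", "censoring_target",
                       "true_shape", "theta_true", "baseline_rate")])
    }),
    failures = lapply(results, function(r) as.list(r$failures))
  )

  out <- structure(
    list(scenarios = results, grid = grid, mse_table = mse_table,
         level_table = level_table, metadata = metadata),
    class = "study_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(out, "table6", file.path(out_dir, "table6_grid.csv"))
    write_table(out, "table7", file.path(out_dir, "table7_mse.csv"))
    write_table(out, "table8", file.path(out_dir, "table8_levels.csv"))
    jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulation study:", nrow(x$grid), "scenarios, backends:",
      paste(x$metadata$backends, collapse = ", "), "\n")
  print(utils::head(x$mse_table, 4), digits = 4)
  invisible(x)
}
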