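# Shared fixtures, all generated in code.

# A small, quick multicenter cohort with a logarithmic learning effect.
small_cohort <- function(seed = 11, theta = 0.25, censoring = 0.10,
                         phys = 5, cases = 20) {
  generate_cohort(scenario_config(
    n_centers = 4, physicians_per_center = phys,
    cases_per_physician = cases, censoring_target = censoring,
    true_shape = "logarithmic", theta_true = theta, seed = seed
  ))
}

# The frailty parameter-recovery design: 30 operators of 40 cases each.
recovery_config <- function(seed, theta = 0.5) {
  scenario_config(n_centers = 5, physicians_per_center = 6,
                  cases_per_physician = 40, censoring_target = 0.10,
                  true_shape = "logarithmic", theta_true = theta,
                  seed = seed)
}

# Independent brute-force maximiser of the Cox partial likelihood (Efron
# reduces to Breslow here: no ties) for a single covariate.
grid_cox_beta <- function(time, event, x, lo = -3, hi = 3, n = 200001) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  pl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(lo, hi, length.out = n)
  grid[which.max(vapply(grid, pl, numeric(1)))]
}
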