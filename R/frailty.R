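#' Shared gamma-frailty Cox model fit by EM with a profile likelihood
#'
#' Fits the shared-frailty proportional hazards model in which all
#' procedures of operator `j` share an unobserved multiplicative effect
#' `w_j` on the hazard, `Lambda_ij(t | w_j) = w_j * Lambda_0(t) *
#' exp(beta' x_ij)`, with `w_j ~ Gamma(mean 1, variance theta)`.
#'
#' For fixed `theta` the fit alternates an E-step, in which the posterior
#' frailty means are `E[w_j] = (1/theta + D_j) / (1/theta + H_j)` with
#' `D_j` the cluster's event count and `H_j = sum_i Lambda0(t_i) exp(beta'
#' x_i)` its accumulated hazard, and an M-step Cox fit with `log w_j` as an
#' offset (Efron ties, Breslow baseline).  Fitted frailties are rescaled to
#' mean 1 at every E-step; the baseline absorbs the scale, to which the
#' marginal likelihood is invariant.  `theta` itself is estimated by
#' maximising the profiled gamma-frailty marginal log-likelihood over a
#' coarse grid refined by golden-section search.  The frailty p-value is a
#' boundary likelihood-ratio test of `theta = 0` against the 50:50
#' chi-squared (0, 1 df) mixture null.
#'
#' @param cohort cohort data frame with `time` and `event` columns.
#' @param covariates covariate column names.
#' @param cluster column name of the frailty grouping (e.g. operator id).
#' @param strata optional column name defining baseline strata.
#' @param theta fix the frailty variance instead of estimating it
#'   (`theta = 0` reduces to [fit_cox()] without the robust variance).
#' @param eps relative marginal log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations per theta evaluation.
#' @param theta_max upper bound of the profile search.
#' @return An object of class `frailty_fit` (inherits `cox_fit`): `beta`,
#'   `se_naive`, `theta`, `frailties` (named, mean 1), `frailty_pvalue`,
#'   `loglik` (marginal), `loglik_null`, per-stratum Breslow `baseline`,
#'   and an iteration `trace`.
#' @export
fit_frailty <- function(cohort, covariates, cluster, strata = NULL,
                        theta = NULL, eps = 1e-8, maxit = 200,
                        theta_max = 4) {
  d <- as.data.frame(cohort)
  if (sum(d$event) < 1) stop("need at least one event")
  cl <- as.factor(d[[cluster]])
  if (nlevels(cl) < 2) stop("frailty fit needs at least two clusters")
  X <- build_design(d, covariates)
  strat <- if (!is.null(strata)) as.factor(d[[strata]]) else NULL
  st <- new.env(parent = emptyenv())
  st$w <- rep(1, nlevels(cl))
  st$trace <- data.frame(theta = numeric(0), loglik = numeric(0),
                         iters = integer(0))

  em <- em_gamma_frailty(d$time, d$event, X, cl, strat, covariates,
                         eps = eps, maxit = maxit)

  fit0 <- em(0, rep(1, nlevels(cl)))

  if (!is.null(theta)) {
    est <- if (theta == 0) fit0 else em(theta, st$w)
    theta_hat <- theta
  } else {
    profile <- function(th) {
      f <- em(th, st$w)
      st$w <- f$w
      st$trace <- rbind(st$trace,
                        data.frame(theta = th, loglik = f$loglik,
                                   iters = f$iters))
      f$loglik
    }
    grid <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, min(3.2, theta_max))
    grid <- grid[grid <= theta_max]
    pl <- vapply(grid, profile, numeric(1))
    if (max(pl) <= fit0$loglik + 1e-10) {
      theta_hat <- 0
      est <- fit0
    } else {
      k <- which.max(pl)
      lo <- if (k == 1) 1e-6 else grid[k - 1]
      hi <- if (k == length(grid)) theta_max else grid[k + 1]
      opt <- stats::optimize(profile, c(lo, hi), maximum = TRUE,
                             tol = 1e-3)
      if (opt$objective >= pl[k]) {
        theta_hat <- opt$maximum
      } else {
        theta_hat <- grid[k]
      }
      est <- em(theta_hat, st$w)
      if (est$loglik <= fit0$loglik + 1e-10) {
        theta_hat <- 0
        est <- fit0
      }
    }
  }

  lrt <- max(0, 2 * (est$loglik - fit0$loglik))
  pval <- if (theta_hat <= 0 || lrt <= 0) {
    1
  } else {
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }

  w <- est$w
  names(w) <- levels(cl)
  structure(
    list(beta = est$beta, se_naive = est$se, se_robust = est$se,
         theta = theta_hat, frailties = w, frailty_pvalue = pval,
         loglik = est$loglik, loglik_null = fit0$loglik,
         covariates = covariates, cluster_var = cluster,
         strata_var = strata, baseline = est$baseline,
         iterations = est$iters, trace = st$trace),
    class = c("frailty_fit", "cox_fit")
  )
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat(sprintf(
    "Shared gamma-frailty Cox model: theta = %.4f (frailty p = %.4g), %d clusters\n",
    x$theta, x$frailty_pvalue, length(x$frailties)))
  print(data.frame(coef = round(x$beta, 4), HR = round(exp(x$beta), 4),
                   se = round(x$se_naive, 4)))
  invisible(x)
}

## Factory returning an EM solver closure over fixed data.  For theta = 0
## the solver is a single plain Cox fit.  Returns per call: beta, se, w
## (posterior frailty means, rescaled to mean 1), baseline (Breslow per
## stratum), marginal loglik, iters.
em_gamma_frailty <- function(time, event, X, cl, strat, covariates,
                             eps, maxit) {
  cl_i <- as.integer(cl)
  n_cl <- nlevels(cl)
  D <- as.numeric(tapply(event, cl_i, sum))
  D[is.na(D)] <- 0
  strat_chr <- if (is.null(strat)) rep("all", length(time)) else as.character(strat)

  mstep <- function(w, beta_init) {
    off <- log(w)[cl_i]
    fit <- survival::coxph.fit(
      x = X, y = survival::Surv(time, event),
      strata = if (is.null(strat)) NULL else as.integer(strat),
      offset = off, init = beta_init,
      control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL
    )
    beta <- fit$coefficients
    if (any(is.na(beta))) stop("singular design in frailty M-step")
    lp_full <- as.numeric(X %*% beta) + off
    base <- breslow_cumhaz(time, event, lp_full,
                           if (is.null(strat)) NULL else strat)
    ## cumulative hazard at each subject's time, frailty excluded
    ch <- numeric(length(time))
    for (s in names(base)) {
      idx <- strat_chr == s
      ch[idx] <- eval_cumhaz(base[[s]], time[idx])
    }
    Hi <- ch * exp(as.numeric(X %*% beta))
    H <- as.numeric(tapply(Hi, cl_i, sum))
    H[is.na(H)] <- 0
    ## log Breslow increment at each event's time, for the likelihood
    ev_loghaz <- 0
    for (s in names(base)) {
      idx <- strat_chr == s & event == 1
      if (!any(idx)) next
      b <- base[[s]]
      hz <- b$haz[match(time[idx], b$time)]
      ev_loghaz <- ev_loghaz + sum(log(hz))
    }
    ev_lp <- sum((X %*% beta)[event == 1])
    list(beta = beta, var = fit$var, H = H,
         ev_term = ev_loghaz + ev_lp, baseline = base)
  }

  marginal_loglik <- function(theta, ms) {
    if (theta <= 0) return(ms$ev_term - sum(ms$H))
    nu <- 1 / theta
    ms$ev_term + sum(
      nu * log(nu) - lgamma(nu) + lgamma(nu + D) -
        (nu + D) * log(nu + ms$H)
    )
  }

  function(theta, w_init) {
    if (theta <= 0) {
      ms <- mstep(rep(1, n_cl), NULL)
      return(list(beta = stats::setNames(ms$beta, covariates),
                  se = sqrt(diag(as.matrix(ms$var))),
                  w = rep(1, n_cl), baseline = ms$baseline,
                  loglik = marginal_loglik(0, ms), iters = 1L))
    }
    w <- w_init
    beta <- NULL
    ll_old <- -Inf
    ll_hist <- numeric(0)
    for (it in seq_len(maxit)) {
      ms <- mstep(w, beta)
      beta <- ms$beta
      ll <- marginal_loglik(theta, ms)
      ll_hist <- c(ll_hist, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < eps * (abs(ll_old) + 1e-3)) {
        w_new <- (1 / theta + D) / (1 / theta + ms$H)
        w <- w_new / mean(w_new)
        return(list(beta = stats::setNames(beta, covariates),
                    se = sqrt(diag(as.matrix(ms$var))),
                    w = w, baseline = ms$baseline, loglik = ll,
                    iters = it))
      }
      ll_old <- ll
      w_new <- (1 / theta + D) / (1 / theta + ms$H)
      w <- w_new / mean(w_new)
    }
    cond <- structure(
      class = c("survlc_nonconvergence", "error", "condition"),
      list(message = paste0("frailty EM did not converge in ", maxit,
                            " iterations at theta = ", signif(theta, 4)),
           call = sys.call(-1), trace = ll_hist)
    )
    stop(cond)
  }
}
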