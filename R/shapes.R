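#' Parametric learning-curve shapes
#'
#' Four classical parametric families describe how the probability of
#' procedural success changes with an operator's cumulative case volume
#' `n`: a rapid-rise-then-plateau exponential, a power series, an unbounded
#' logarithmic ramp, and a sigmoidal log-normal.  All shapes are anchored at
#' a starting probability `start` for the first case and (except the
#' logarithmic, which is clamped) approach an asymptote `asymptote`.
#'
#' Parameterisations, for case order `n >= 1`:
#' \describe{
#'   \item{exponential}{`a - (a - b) * exp(-c * (n - 1))`}
#'   \item{power_series}{`a - (a - b) * n^(-c)`}
#'   \item{logarithmic}{`b + c * log(n)`, clamped to `[0, 1]`}
#'   \item{log_normal}{`b + (a - b) * pnorm((log(n) - mu) / sigma)`}
#' }
#' with `a = asymptote`, `b = start`, `c = rate`.  Values are always clamped
#' to the probability scale `[0, 1]`.
#'
#' @param kind one of `"exponential"`, `"power_series"`, `"logarithmic"`,
#'   `"log_normal"`.
#' @param asymptote plateau probability `a` in `[0, 1]`.
#' @param start first-case probability `b` in `[0, 1]`.
#' @param rate learning rate `c >= 0`.
#' @param mu,sigma log-scale location and spread of the log-normal shape
#'   (ignored by the other kinds); `sigma > 0`.
#' @return An object of class `shape_spec`.
#' @examples
#' sp <- shape_spec("exponential", asymptote = 0.9, start = 0.5, rate = 0.2)
#' shape_value(sp, 1:10)
#' @export
shape_spec <- function(kind = shape_kinds(), asymptote = 0.9, start = 0.5,
                       rate = 0.15, mu = log(8), sigma = 1) {
  kind <- match.arg(kind)
  if (asymptote < 0 || asymptote > 1) stop_invalid("asymptote must be in [0,1]")
  if (start < 0 || start > 1) stop_invalid("start must be in [0,1]")
  if (rate < 0) stop_invalid("rate must be >= 0")
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  structure(
    list(kind = kind, asymptote = asymptote, start = start, rate = rate,
         mu = mu, sigma = sigma),
    class = "shape_spec"
  )
}

#' The four supported learning-curve families
#' @return Character vector of shape names.
#' @export
shape_kinds <- function() {
  c("exponential", "power_series", "logarithmic", "log_normal")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat("Learning-curve shape:", x$kind, "\n")
  if (x$kind == "logarithmic") {
    cat(sprintf("  start %.4f, slope %.4f (clamped to [0,1])\n",
                x$start, x$rate))
  } else if (x$kind == "log_normal") {
    cat(sprintf("  start %.4f -> asymptote %.4f, mu %.4f, sigma %.4f\n",
                x$start, x$asymptote, x$mu, x$sigma))
  } else {
    cat(sprintf("  start %.4f -> asymptote %.4f, rate %.4f\n",
                x$start, x$asymptote, x$rate))
  }
  invisible(x)
}

#' Evaluate a learning-curve shape at given case orders
#'
#' @param spec a [shape_spec()].
#' @param n case order(s), `>= 1`.
#' @return Success probabilities in `[0, 1]`, one per element of `n`.
#' @export
shape_value <- function(spec, n) {
  stopifnot(inherits(spec, "shape_spec"))
  if (any(n < 1)) stop("case order must be >= 1")
  a <- spec$asymptote
  b <- spec$start
  cc <- spec$rate
  raw <- switch(spec$kind,
    exponential  = a - (a - b) * exp(-cc * (n - 1)),
    power_series = a - (a - b) * n^(-cc),
    logarithmic  = b + cc * log(n),
    log_normal   = b + (a - b) * stats::pnorm((log(n) - spec$mu) / spec$sigma)
  )
  clamp01(raw)
}

## Residual sum of squares of a parameter vector for one kind.
## par layout: exponential/power_series: (a, b, c); logarithmic: (b, c);
## log_normal: (a, b, mu, sigma).
shape_rss <- function(par, kind, n, y) {
  spec <- par_to_spec(par, kind)
  sum((shape_value(spec, n) - y)^2)
}

par_to_spec <- function(par, kind) {
  switch(kind,
    exponential  = ,
    power_series = shape_spec(kind, asymptote = par[1], start = par[2],
                              rate = par[3]),
    logarithmic  = shape_spec(kind, asymptote = 1, start = par[1],
                              rate = par[2]),
    log_normal   = shape_spec(kind, asymptote = par[1], start = par[2],
                              rate = 0, mu = par[3], sigma = par[4])
  )
}

shape_bounds <- function(kind, n_max) {
  switch(kind,
    exponential  = ,
    power_series = list(lower = c(0, 0, 1e-8), upper = c(1, 1, 10)),
    logarithmic  = list(lower = c(0, 0), upper = c(1, 10)),
    log_normal   = list(lower = c(0, 0, -2, 0.05),
                        upper = c(1, 1, log(n_max) + 2, 10))
  )
}

## For a fixed nonlinear parameter the shape is linear in (a, b) (or (b, c)
## for the logarithmic), so the grid stage solves tiny least-squares problems
## and only the polish is a box-constrained quasi-Newton.
shape_grid_starts <- function(kind, n, y) {
  n_max <- max(n)
  lin2 <- function(u) {
    ## y = a*(1-u) + b*u
    X <- cbind(1 - u, u)
    ab <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), mean(y)))
    clamp01(ab)
  }
  starts <- list()
  if (kind %in% c("exponential", "power_series")) {
    for (cc in exp(seq(log(0.005), log(5), length.out = 40))) {
      u <- if (kind == "exponential") exp(-cc * (n - 1)) else n^(-cc)
      ab <- lin2(u)
      starts[[length(starts) + 1L]] <- c(ab[1], ab[2], cc)
    }
  } else if (kind == "logarithmic") {
    X <- cbind(1, log(n))
    bc <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), 0))
    starts[[1L]] <- c(clamp01(bc[1]), min(10, max(0, bc[2])))
    starts[[2L]] <- c(clamp01(min(y)), 0.1)
  } else { # log_normal
    for (mu in seq(0, log(n_max) + 0.5, length.out = 12)) {
      for (sg in c(0.25, 0.5, 1, 2, 4)) {
        u <- stats::pnorm((log(n) - mu) / sg)
        ab <- lin2(u)
        starts[[length(starts) + 1L]] <- c(ab[1], ab[2], mu, sg)
      }
    }
  }
  starts
}

#' Fit a learning-curve shape by nonlinear least squares
#'
#' Box-constrained least squares with a deterministic profile grid over the
#' nonlinear parameter(s) plus seeded random multi-starts, polished by
#' L-BFGS-B; the best local optimum is returned.
#'
#' @param orders case orders (`>= 1`).
#' @param probabilities observed or predicted success probabilities.
#' @param kind shape family, see [shape_kinds()].
#' @param n_starts number of additional random starts (default 5).
#' @param seed seed for the random starts.
#' @return A list with elements `spec` (the fitted [shape_spec()]), `rss`
#'   (residual sum of squares) and `fitted` (fitted values at `orders`).
#' @export
fit_shape <- function(orders, probabilities, kind = shape_kinds(),
                      n_starts = 5, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(orders) == length(probabilities))
  if (any(orders < 1)) stop("case order must be >= 1")
  n_par <- if (kind == "logarithmic") 2L else if (kind == "log_normal") 4L else 3L
  if (length(unique(orders)) < n_par) {
    stop("need at least ", n_par, " distinct case orders to fit a ",
         kind, " shape")
  }
  y <- as.numeric(probabilities)
  n <- as.numeric(orders)

  if (max(y) - min(y) < 1e-12) {
    ## degenerate flat input: return a flat shape with zero residual
    flat <- shape_spec(kind, asymptote = clamp01(y[1]), start = clamp01(y[1]),
                       rate = if (kind == "logarithmic") 0 else 1e-6)
    return(list(spec = flat, rss = sum((shape_value(flat, n) - y)^2),
                fitted = shape_value(flat, n)))
  }

  bounds <- shape_bounds(kind, max(n))
  starts <- shape_grid_starts(kind, n, y)
  rnd <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    stats::runif(length(bounds$lower), bounds$lower,
                 pmin(bounds$upper, c(1, 1, 3, 3)[seq_along(bounds$lower)]))
  }))
  ## polish only the most promising grid candidates; the grid RSS itself is
  ## cheap to evaluate and a reliable ranking on these small problems
  if (length(starts) > 3) {
    grid_rss <- vapply(starts, function(p) {
      shape_rss(pmin(bounds$upper, pmax(bounds$lower, p)), kind, n, y)
    }, numeric(1))
    starts <- starts[order(grid_rss)[seq_len(3)]]
  }
  starts <- c(starts, rnd)

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(bounds$upper, pmax(bounds$lower, p0))
    fit <- tryCatch(
      stats::optim(p0, shape_rss, kind = kind, n = n, y = y,
                   method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper,
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("shape fit failed for kind '", kind, "'")
  spec <- par_to_spec(best$par, kind)
  list(spec = spec, rss = best$value, fitted = shape_value(spec, n))
}
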