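#' @keywords internal
"_PACKAGE"

## NULL coalescing, used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state so seeded internals do
#' not disturb the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_invalid <- function(...) {
  stop(structure(
    class = c("survlc_invalid_config", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Exact integral of a right-continuous survival step function over [0, tau]
#'
#' `times` are the jump locations; `surv` the value just after each jump;
#' the function is 1 on [0, times[1]).
#' @noRd
integrate_step <- function(times, surv, tau) {
  stopifnot(length(times) == length(surv), tau > 0)
  keep <- times < tau
  t_k <- c(0, times[keep])
  s_k <- c(1, surv[keep])
  widths <- diff(c(t_k, tau))
  sum(s_k * widths)
}

mse <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  mean((a - b)^2)
}
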