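# internal numeric helpers shared across modules

# trapezoid quadrature on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# uniform-grid check; tolerance relative to the median step
is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 2L) return(FALSE)
  dt <- diff(t)
  all(dt > 0) && (max(dt) - min(dt)) <= tol * stats::median(dt)
}

grid_step <- function(t) (t[length(t)] - t[1]) / (length(t) - 1L)

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
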