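# Internal numerical helpers shared across modules.

# Periodic Gaussian bump on the unit circle: smooth, exactly periodic in phase.
pbump <- function(phase, center, width) {
  exp(-((phase - center) / width)^2) +
    exp(-((phase - center - 1) / width)^2) +
    exp(-((phase - center + 1) / width)^2)
}

# Trapezoidal integral of y(t) over possibly non-uniform t.
trapz_int <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

# First derivative by central differences, one-sided at the endpoints.
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 3L) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Second derivative by central differences; endpoints copy their neighbour,
# which is adequate because every consumer works on low-pass-filtered signals.
second_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 3L) return(d)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

# z-component of the cross product r x F for 2D row-wise matrices.
cross_z <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}
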