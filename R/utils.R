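# internal numerical utilities

# Thomas algorithm for a tridiagonal system.
# a: sub-diagonal (n-1), b: diagonal (n), cc: super-diagonal (n-1), d: rhs (n)
tridiag_solve <- function(a, b, cc, d) {
  n <- length(b)
  if (n == 1L) return(d / b)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- cc[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (j in 2:n) {
    m <- b[j] - a[j - 1] * cp[j - 1]
    if (j < n) cp[j] <- cc[j] / m
    dp[j] <- (d[j] - a[j - 1] * dp[j - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (j in (n - 1):1) x[j] <- dp[j] - cp[j] * x[j + 1]
  x
}

# Bernoulli function B(t) = t / (exp(t) - 1), the exponential-fitting weight
# of the Scharfetter-Gummel flux; series expansion near t = 0.
bernoulli_fn <- function(t) {
  out <- numeric(length(t))
  small <- abs(t) < 1e-5
  ts <- t[small]
  out[small] <- 1 - ts / 2 + ts * ts / 12
  tb <- t[!small]
  out[!small] <- tb / expm1(tb)
  out
}

# trapezoidal integral
trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Piecewise-linear table interpolation with optional constant-value clamping.
# tab: data.frame whose first column is the (strictly increasing) abscissa.
interp_table <- function(tab, col, x, extrapolate = FALSE, what = col) {
  if (is.null(tab) || nrow(tab) == 0)
    stop("configuration error: table for '", what, "' is empty or missing")
  xs <- tab[[1]]
  ys <- tab[[col]]
  if (any(diff(xs) <= 0))
    stop("configuration error: table grid for '", what,
         "' must be strictly increasing")
  if (!extrapolate && (any(x < min(xs) - 1e-12) || any(x > max(xs) + 1e-12)))
    stop("range error: requested concentration outside the '", what,
         "' table range [", min(xs), ", ", max(xs), "]; set extrapolate = TRUE",
         " to clamp")
  stats::approx(xs, ys, xout = x, rule = 2)$y
}
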