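# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the OLS oracle uses the explicit normal
# equations, the root oracle uses stats::uniroot on a hand-built bracket,
# and the probe-signal oracle evaluates the trigonometric sum term by term.

# Normal-equations least squares: beta = (X'X)^-1 X'y.
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Scalar root of c x + d sign(x)|x|^p = t, via uniroot on a sign-change
# bracket found by scanning outward.
root_oracle <- function(cc, dd, t, p = 0.3) {
  g <- function(x) cc * x + dd * sign(x) * abs(x)^p
  f <- function(x) g(x) - t
  grid <- sort(unique(c(-10^seq(-12, 9, by = 0.05), 0, 10^seq(-12, 9, by = 0.05))))
  fg <- f(grid)
  i <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  stopifnot(!is.na(i))
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
}

# Term-by-term evaluation of the probe signal.
signal_oracle <- function(k) {
  out <- numeric(length(k))
  for (per in c(100, 80, 60, 40)) out <- out + sin(k / per)
  for (per in c(90, 70, 50, 30)) out <- out + cos(k / per)
  10 * out
}

# A well-spread deterministic regression design for fit tests: positive
# series covering a wide PU range so all four basis columns are separated.
toy_rows <- function(n = 60, a = 0.5, b = 1.0, cc = 0.8, d = 2.0, p = 0.3,
                     seed = 101) {
  set.seed(seed)
  u <- exp(runif(n, log(20), log(500)))
  y <- numeric(n)
  y[1] <- 100
  for (k in 2:n)
    y[k] <- a * y[k - 1] + b * y[k - 1]^p + cc * u[k] + d * u[k]^p
  X <- cbind(y_lag = y[-n], y_lag_pow = y[-n]^p, u = u[-1], u_pow = u[-1]^p)
  list(X = X, y = y[-1], truth = c(a = a, b = b, c = cc, d = d))
}

# Small noiseless control-group dataset shared by several tests.
noiseless_dataset <- function(n_subjects = 2, seed = 99, direction = "L->R") {
  simulate_group(protocol_layout(), ground_truth(noise_sd_PU = 0),
                 "C", n_subjects, seed, direction = direction)
}
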