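## Independent brute-force oracles. These deliberately avoid the package's
## matcher internals: curves are evaluated analytically and the optimum is
## found by exhaustive grid search.

## Exhaustive 0.01 mm grid search for the displacement t of `meas_fun`
## relative to `ref_fun` (both analytic functions of x), minimizing the
## sum of squared differences over the window points.
brute_force_shift <- function(ref_fun, meas_fun, win_x, search = 15,
                              step = 0.01) {
  shifts <- seq(-search, search, by = step)
  ssd <- vapply(shifts, function(t)
    sum((meas_fun(win_x) - ref_fun(win_x - t))^2), numeric(1))
  shifts[which.min(ssd)]
}

## Numeric-convolution oracle for the analytic IDD shape: unconvolved
## step-plus-exponential peak on a fine grid, convolved with a Gaussian
## straggling kernel by direct summation.
numeric_idd <- function(r_eval, sigma, peak_amp = 11, tail_tau = 12) {
  step <- 0.02
  u <- seq(-8 * sigma, 8 * sigma, by = step)
  kern <- dnorm(u, sd = sigma) * step
  vapply(r_eval, function(r) {
    raw <- ifelse(r - u >= 0, 1 + peak_amp * exp(-(r - u) / tail_tau), 0)
    sum(raw * kern)
  }, numeric(1))
}

## Plain-R weighted scenario statistics, written directly from the
## formulas, as an independent check of weighted_stats().
naive_weighted_stats <- function(m, w, g) {
  mu <- sum(w * m) / sum(w)
  s2 <- sum(w) / (sum(w)^2 - sum(w^2)) * sum(w * (m - mu)^2)
  c(mu = mu, sigma2 = s2, a = mu - g)
}
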