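# Independent oracles used to check package computations.

# Dense finite-difference minimizer of the smoothing-spline functional
#   p * sum_i (y_i - f(x_i))^2 + (1 - p) * int f''(t)^2 dt
# over function values on a fine uniform grid. Solves the quadratic
# problem exactly; approximates the natural smoothing spline without
# using any spline machinery.
dense_smoothing_oracle <- function(x, y, p, ngrid = 2001) {
  xs <- seq(min(x), max(x), length.out = ngrid)
  h <- xs[2] - xs[1]
  idx <- vapply(x, function(v) which.min(abs(xs - v)), integer(1))
  # second-difference operator (interior points)
  D <- matrix(0, ngrid - 2, ngrid)
  for (k in seq_len(ngrid - 2))
    D[k, k:(k + 2)] <- c(1, -2, 1) / h^2
  A <- (1 - p) * h * crossprod(D)
  b <- numeric(ngrid)
  for (k in seq_along(idx)) {
    A[idx[k], idx[k]] <- A[idx[k], idx[k]] + p
    b[idx[k]] <- b[idx[k]] + p * y[k]
  }
  f <- solve(A, b)
  list(x = xs, f = f, at = function(v) f[which.min(abs(xs - v))])
}

# Closed-form simple OLS via the normal equations.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Brute-force decoder: enumerate every admissible distribution on the
# grid (all single speeds; all even-step pairs within the separation
# range with weights on the probability lattice) and return the best
# objective. Independent of the package's search: scores candidates by
# direct construction of the estimated population response.
brute_force_decode <- function(setup, spRP, sep_min = 2, sep_max = 96,
                               prob_step = 0.1) {
  n <- setup$grid$n
  best <- -Inf
  best_dist <- NULL
  for (j in seq_len(n)) {
    of <- -sum((setup$G[, j] - spRP)^2)
    if (of > best) { best <- of; best_dist <- list(j = j, w = 1) }
  }
  wlat <- seq(0, 1, by = prob_step)
  for (s in seq(sep_min, min(sep_max, n - 1), by = 2)) {
    k <- s / 2
    for (ctr in seq_len(n)) {
      jlo <- ctr - k; jhi <- ctr + k
      if (jlo < 1 || jhi > n) next
      for (w in wlat) {
        est <- w * setup$G[, jlo] + (1 - w) * setup$G[, jhi]
        of <- -sum((est - spRP)^2)
        if (of > best) { best <- of; best_dist <- list(j = c(jlo, jhi), w = w) }
      }
    }
  }
  list(of = best, dist = best_dist)
}
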