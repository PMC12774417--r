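#' Percent variance explained by a model curve
#'
#' `PV = 100 * (1 - SSE/SST)` where SSE is the sum of squared errors
#' between model and data and SST the sum of squared deviations of the
#' data about its mean.
#'
#' @param model_curve,data_curve equal-length numeric vectors.
#' @return percent (at most 100; negative when the model is worse than the
#'   data mean).
#' @export
percent_variance <- function(model_curve, data_curve) {
  if (length(model_curve) != length(data_curve))
    stop("curves must have equal length")
  sst <- sum((data_curve - mean(data_curve))^2)
  if (sst <= 0) stop("data curve has zero variance")
  100 * (1 - sum((model_curve - data_curve)^2) / sst)
}

#' Align a direction-tuning curve to a neuron's preferred direction
#'
#' Circularly shifts a direction-tuning curve sampled on a uniform grid
#' covering 360 degrees so that the preferred direction maps to 0 degrees,
#' interpolating with a periodic cubic spline. On-grid shifts reduce to an
#' exact cyclic permutation of the samples.
#'
#' @param directions uniform direction grid in degrees covering 360.
#' @param rates responses at `directions`.
#' @param preferred_direction degrees; the direction mapped to 0.
#' @return rates of the shifted curve on the same `directions` grid.
#' @export
align_direction_tuning <- function(directions, rates, preferred_direction) {
  n <- length(directions)
  step <- diff(directions)
  if (n < 3 || any(abs(step - step[1]) > 1e-8) ||
      abs(n * step[1] - 360) > 1e-6)
    stop("directions must be a uniform grid covering 360 degrees")
  x <- c(directions, directions[1] + 360)
  y <- c(rates, rates[1])
  xout <- (directions + preferred_direction - directions[1]) %% 360 + directions[1]
  stats::spline(x, y, method = "periodic", xout = xout)$y
}

#' Component weights implied by the weighting-pool normalization model
#'
#' `w_s = S_s^n / (S_s^n + alpha S_f^n + sigma)` and
#' `w_f = S_f^n / (S_s^n + alpha S_f^n + sigma)`, computed stably in the
#' log domain so large exponents `n` do not overflow.
#'
#' @param n soft-max exponent of the pool responses, in \[0.01, 100\].
#' @param sigma semi-saturation constant of the normalization, \[0, 500\].
#' @param alpha tuned-normalization scaling of the faster pool term,
#'   \[0.01, 100\].
#' @param S_s,S_f weighting-pool responses (spikes/s) to the slower and
#'   faster component speeds.
#' @return named vector `c(w_s = ..., w_f = ...)`.
#' @export
normalization_weights <- function(n, sigma, alpha, S_s, S_f) {
  ls <- n * log(S_s)
  lf <- n * log(S_f)
  M <- max(ls, lf)
  den <- exp(ls - M) + alpha * exp(lf - M) + sigma * exp(-M)
  c(w_s = exp(ls - M) / den, w_f = exp(lf - M) / den)
}

#' Fit the linear weighted-sum (LWS) model to bi-speed direction tuning
#'
#' Fits `R_bi(theta) = w_s R_s(theta1) + w_f R_f(theta2) + c` by least
#' squares with the offset constrained to \[0, 100\] spikes/s; the weights
#' are unconstrained (the direction-tuning curves constrain the fit well
#' enough that a sum-to-one constraint is unnecessary). Because the model
#' is linear, the constrained optimum is found exactly: the unconstrained
#' OLS solution if its offset is feasible, otherwise OLS with the offset
#' clamped at the violated bound.
#'
#' @param data a direction-tuning set: data frame with columns
#'   `va_direction`, `r_slower`, `r_faster`, `r_bi` sampled on a common
#'   vector-average direction grid (see [make_direction_tuning()]).
#' @return list of class `"lws_fit"`: `w_s`, `w_f`, `c`, `pv` (percent
#'   variance explained) and `fitted`.
#' @export
fit_lws <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 directions")
  fit <- stats::lm(r_bi ~ r_slower + r_faster, data = data)
  cf <- stats::coef(fit)
  c_hat <- unname(cf[1])
  if (c_hat < 0 || c_hat > 100) {
    c_hat <- max(0, min(100, c_hat))
    fit <- stats::lm(I(r_bi - c_hat) ~ r_slower + r_faster - 1, data = data)
    cf <- c(c_hat, stats::coef(fit))
    fitted_vals <- c_hat + as.numeric(stats::fitted(fit))
  } else {
    fitted_vals <- as.numeric(stats::fitted(fit))
  }
  structure(list(w_s = unname(cf[2]), w_f = unname(cf[3]), c = c_hat,
                 pv = percent_variance(fitted_vals, data$r_bi),
                 fitted = fitted_vals),
            class = "lws_fit")
}

#' Fit the weighting-pool divisive-normalization model
#'
#' Fits `R_bi(theta) = w_s(n, sigma, alpha) R_s(theta1) +
#' w_f(n, sigma, alpha) R_f(theta2) + c`, where the component weights are
#' set by the pool responses through [normalization_weights()]. Parameters
#' are bounded (`0.01 <= n <= 100`, `0 <= sigma <= 500`,
#' `0.01 <= alpha <= 100`, `0 <= c <= 100`) and the sum of squared errors
#' is minimized by bounded quasi-Newton (L-BFGS-B) from `n_restarts`
#' random interior starts; the best solution is kept.
#'
#' @inheritParams fit_lws
#' @param pool list or vector with pool responses `S_s` and `S_f`
#'   (spikes/s, positive).
#' @param n_restarts random restarts (default 20).
#' @param seed seed for the restart draws.
#' @return list of class `"normalization_fit"`: `n`, `sigma`, `alpha`,
#'   `c`, `implied_w_s`, `implied_w_f`, `pv`, `sse`, `fitted`.
#' @export
fit_normalization <- function(data, pool, n_restarts = 20, seed = 1L) {
  pool <- as.list(pool)
  S_s <- pool$S_s
  S_f <- pool$S_f
  if (is.null(S_s) || is.null(S_f) || S_s <= 0 || S_f <= 0)
    stop("pool must provide positive S_s and S_f")
  lower <- c(n = 0.01, sigma = 0, alpha = 0.01, c = 0)
  upper <- c(n = 100, sigma = 500, alpha = 100, c = 100)
  sse_fun <- function(par) {
    w <- normalization_weights(par[1], par[2], par[3], S_s, S_f)
    pred <- w["w_s"] * data$r_slower + w["w_f"] * data$r_faster + par[4]
    sum((pred - data$r_bi)^2)
  }
  set.seed(seed)
  # mild starts: n and alpha log-uniform, sigma/c uniform in range
  starts <- cbind(exp(stats::runif(n_restarts, log(0.1), log(20))),
                  stats::runif(n_restarts, 0, 300),
                  exp(stats::runif(n_restarts, log(0.1), log(10))),
                  stats::runif(n_restarts, 0, 20))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], sse_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("normalization fit failed to converge from all restarts")
  par <- best$par
  w <- normalization_weights(par[1], par[2], par[3], S_s, S_f)
  fitted_vals <- w["w_s"] * data$r_slower + w["w_f"] * data$r_faster + par[4]
  structure(list(n = unname(par[1]), sigma = unname(par[2]),
                 alpha = unname(par[3]), c = unname(par[4]),
                 implied_w_s = unname(w["w_s"]), implied_w_f = unname(w["w_f"]),
                 pv = percent_variance(fitted_vals, data$r_bi),
                 sse = best$value, fitted = as.numeric(fitted_vals)),
            class = "normalization_fit")
}
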