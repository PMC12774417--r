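#' Log-mean speed of a speed pair
#'
#' The geometric mean `exp((ln v1 + ln v2)/2) = sqrt(v1 v2)`, the single
#' speed used as the comparison stimulus for a bi-speed pair.
#'
#' @param v1,v2 speeds in deg/s, positive.
#' @return speed in deg/s.
#' @examples
#' log_mean_speed(2.5, 10)  # 5
#' @export
log_mean_speed <- function(v1, v2) {
  if (any(v1 <= 0) || any(v2 <= 0)) stop("speeds must be positive")
  exp((log(v1) + log(v2)) / 2)
}

#' Bi-speed stimulus condition
#'
#' @param v_s,v_f slower and faster component speeds (deg/s), `v_f > v_s`.
#' @return list of class `"bispeed_condition"` with `v_s`, `v_f`,
#'   `separation_factor` and `log_mean_speed`.
#' @export
bispeed_condition <- function(v_s, v_f) {
  if (v_s <= 0 || v_f <= v_s) stop("need v_f > v_s > 0")
  structure(list(v_s = v_s, v_f = v_f,
                 separation_factor = v_f / v_s,
                 log_mean_speed = log_mean_speed(v_s, v_f)),
            class = "bispeed_condition")
}

#' Per-neuron component weights from a bi-speed response
#'
#' Under the weighted-average description `R = w_s R_s + w_f R_f` with
#' `w_s + w_f = 1`, the weights are recovered per neuron as
#' `w_s = (R_f - R)/(R_f - R_s)` and `w_f = (R - R_s)/(R_f - R_s)`.
#' Neurons whose component responses are (numerically) equal leave the
#' weights undefined; those rows are returned as `NA` with `defined =
#' FALSE` rather than silently dropped. Per-neuron weights are diagnostic;
#' the population regression ([estimate_weights_regression()]) is the
#' primary estimator because per-neuron ratios are unstable when
#' `R_f - R_s` is small.
#'
#' @param R,R_s,R_f bi-speed, slower-component and faster-component
#'   trial-averaged rates (spikes/s), equal-length vectors.
#' @param tol responses with `|R_f - R_s| < tol` are flagged undefined.
#' @return data frame with `w_s`, `w_f`, `defined`; where defined,
#'   `w_s + w_f` is exactly 1.
#' @export
component_weights <- function(R, R_s, R_f, tol = 1e-9) {
  defined <- abs(R_f - R_s) >= tol
  w_f <- ifelse(defined, (R - R_s) / (R_f - R_s), NA_real_)
  data.frame(w_s = 1 - w_f, w_f = w_f, defined = defined)
}

#' Population regression estimate of the faster-component weight
#'
#' Ordinary least squares of `(R - R_s)` on `(R_f - R_s)` with intercept,
#' across neurons. When the intercept is near zero the slope approximates
#' the common faster-component weight `w_f`.
#'
#' @inheritParams component_weights
#' @return list of class `"weight_regression"`: `slope` (the estimated
#'   `w_f`), `intercept` (spikes/s), `r_squared`, `ci95_slope` (t-based
#'   half-width), `n_neurons`.
#' @export
estimate_weights_regression <- function(R, R_s, R_f) {
  if (length(R) < 3) stop("need at least 3 neurons")
  x <- R_f - R_s
  y <- R - R_s
  if (stats::var(x) < .Machine$double.eps) stop("degenerate predictor: R_f - R_s has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  half <- stats::qt(0.975, df = fit$df.residual) * sm$coefficients["x", "Std. Error"]
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 ci95_slope = half,
                 n_neurons = length(R)),
            class = "weight_regression")
}

#' @export
print.weight_regression <- function(x, ...) {
  cat(sprintf("Faster-component weight (regression slope): %.3f +/- %.3f (95%% CI)\n",
              x$slope, x$ci95_slope))
  cat(sprintf("Intercept: %.2f spikes/s   R^2: %.3f   n = %d neurons\n",
              x$intercept, x$r_squared, x$n_neurons))
  invisible(x)
}

#' Random-weight simulation control for the weight regression
#'
#' Null control for the regression estimate: each neuron's bi-speed
#' response is simulated as `R_e = a R_f + (1 - a) R_s` with an
#' independent `a ~ Uniform(0, 1)` per neuron, and the same regression of
#' `(R_e - R_s)` on `(R_f - R_s)` is run; the procedure is repeated
#' `n_reps` times. Because `E[a] = 0.5`, the mean simulated slope is 0.5
#' regardless of the population, which calibrates how far a measured slope
#' must sit from 0.5 to indicate a genuine bias.
#'
#' @inheritParams component_weights
#' @param n_reps repetitions (default 1000).
#' @param seed integer seed.
#' @param a_sampler function(n) returning the n per-neuron weights; the
#'   default draws Uniform(0, 1). Exposed so degenerate controls (all
#'   weights fixed) can be simulated.
#' @return list: `mean_slope`, `ci95_slope` (2.5/97.5 percentile interval),
#'   `mean_r2`, `ci95_r2`, and the full `slopes` / `r_squared` vectors.
#' @export
random_weight_control <- function(R_s, R_f, n_reps = 1000, seed = 1L,
                                  a_sampler = stats::runif) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  n <- length(R_s)
  x <- R_f - R_s
  if (stats::var(x) < .Machine$double.eps) stop("degenerate predictor: R_f - R_s has zero variance")
  slopes <- numeric(n_reps)
  r2 <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    a <- a_sampler(n)
    y <- a * x                       # (R_e - R_s) with R_e = a R_f + (1-a) R_s
    fit <- stats::lm(y ~ x)
    slopes[i] <- unname(stats::coef(fit)["x"])
    # degenerate a_samplers give exact fits; the perfect-fit warning from
    # summary.lm is expected there
    r2[i] <- suppressWarnings(summary(fit)$r.squared)
  }
  list(mean_slope = mean(slopes),
       ci95_slope = unname(stats::quantile(slopes, c(0.025, 0.975))),
       mean_r2 = mean(r2),
       ci95_r2 = unname(stats::quantile(r2, c(0.025, 0.975))),
       slopes = slopes, r_squared = r2)
}

#' One-sided bootstrap comparison of measured vs simulated slopes
#'
#' Fraction of simulated slopes at least as large as the measured one,
#' smoothed as `(k + 1)/(n + 1)` so the reported p is never exactly zero.
#'
#' @param measured_slope measured regression slope.
#' @param simulated_slopes vector of slopes from [random_weight_control()].
#' @return p-value for measured > simulated.
#' @export
bootstrap_compare <- function(measured_slope, simulated_slopes) {
  n <- length(simulated_slopes)
  if (n < 1) stop("need at least one simulated slope")
  (sum(simulated_slopes >= measured_slope) + 1) / (n + 1)
}

#' Split-trial control for the weight regression
#'
#' Removes the shared-term artifact in regressing `(R - R_s)` on
#' `(R_f - R_s)`: the slower-component trials are randomly halved into two
#' independent means `R_s1`, `R_s2`; `(R - R_s1)` is regressed on
#' `(R_f - R_s2)` and `(R - R_s2)` on `(R_f - R_s1)` (same split for both
#' orientations), and the procedure is repeated `n_repeats` times. With a
#' genuine weighted-average code the split-trial slope converges to the
#' all-trials slope as the trial count grows.
#'
#' @param trials TrialTable (see [generate_poisson_trials()]) containing
#'   trials for the bi-speed, slower-component and faster-component
#'   conditions.
#' @param bi,slower,faster the `condition_id` values naming the three
#'   conditions in `trials`.
#' @param n_repeats number of random splits (default 50).
#' @param seed integer seed.
#' @return list: `mean_slope`, `sd_slope`, `mean_r2`, and the per-repeat,
#'   per-orientation `slopes` matrix.
#' @export
split_trial_regression <- function(trials, bi = "bi", slower = "slower",
                                   faster = "faster", n_repeats = 50,
                                   seed = 1L) {
  rate <- trials$spike_count / trials$duration
  mean_by <- function(cond) {
    keep <- trials$condition_id == cond
    tapply(rate[keep], trials$neuron_id[keep], mean)
  }
  R <- mean_by(bi)
  R_f <- mean_by(faster)
  ids <- intersect(names(R), names(R_f))

  keep_s <- trials$condition_id == slower
  s_by_neuron <- split(rate[keep_s], trials$neuron_id[keep_s])
  n_s <- vapply(s_by_neuron, length, integer(1))
  bad <- names(s_by_neuron)[n_s < 2]
  if (length(bad) > 0)
    warning("excluding neurons with < 2 slower-component trials: ",
            paste(bad, collapse = ", "))
  ids <- setdiff(intersect(ids, names(s_by_neuron)[n_s >= 2]), bad)
  if (length(ids) < 3) stop("need at least 3 usable neurons")
  R <- R[ids]; R_f <- R_f[ids]; s_by_neuron <- s_by_neuron[ids]

  set.seed(seed)
  slopes <- matrix(NA_real_, n_repeats, 2)
  r2 <- matrix(NA_real_, n_repeats, 2)
  for (rep_i in seq_len(n_repeats)) {
    halves <- lapply(s_by_neuron, function(v) {
      idx <- sample.int(length(v), floor(length(v) / 2))
      c(mean(v[idx]), mean(v[-idx]))
    })
    R_s1 <- vapply(halves, `[`, numeric(1), 1)
    R_s2 <- vapply(halves, `[`, numeric(1), 2)
    fit1 <- stats::lm(I(R - R_s1) ~ I(R_f - R_s2))
    fit2 <- stats::lm(I(R - R_s2) ~ I(R_f - R_s1))
    slopes[rep_i, 1] <- unname(stats::coef(fit1)[2])
    slopes[rep_i, 2] <- unname(stats::coef(fit2)[2])
    r2[rep_i, 1] <- summary(fit1)$r.squared
    r2[rep_i, 2] <- summary(fit2)$r.squared
  }
  list(mean_slope = mean(slopes), sd_slope = stats::sd(as.numeric(slopes)),
       mean_r2 = mean(r2), slopes = slopes)
}
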