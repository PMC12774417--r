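#' Single speeds and bi-speed pairs used throughout the package
#'
#' The study design samples speed on a logarithmic axis: seven single
#' speeds from 1.25 to 80 deg/s in octave steps, five bi-speed pairs at
#' 4x separation and five at 2x separation.
#'
#' @format `study_speeds()` returns the seven single speeds (deg/s).
#'   `study_speed_pairs()` returns a data frame with columns `v_s`, `v_f`,
#'   `separation` and `log_mean` (one row per pair).
#' @export
study_speeds <- function() c(1.25, 2.5, 5, 10, 20, 40, 80)

#' @rdname study_speeds
#' @export
study_speed_pairs <- function() {
  v_s <- c(1.25, 2.5, 5, 10, 20, 1.25, 2.5, 5, 10, 20)
  v_f <- c(5, 10, 20, 40, 80, 2.5, 5, 10, 20, 40)
  data.frame(
    v_s = v_s, v_f = v_f,
    separation = v_f / v_s,
    log_mean = log_mean_speed(v_s, v_f)
  )
}

#' Generate a synthetic population of speed-tuned model neurons
#'
#' Draws `n_neurons` model neurons whose speed tuning is log-Gaussian
#' (Gaussian in ln speed) with an additive baseline, emulating the tuning
#' statistics of a recorded MT sample. The default preferred-speed
#' distribution is a log-normal, ln(PS) ~ N(ln 18, 1.5), truncated to the
#' full speed range \[1.25, 80\] deg/s; under it the population-average
#' tuning curve peaks near 20 deg/s and roughly 7% / 61% / 32% of neurons
#' prefer speeds below 2.5, between 2.5 and 25, and above 25 deg/s.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param pref_dist preferred-speed distribution: a list with element
#'   `kind`, one of `"lognormal"` (fields `meanlog`, `sdlog`, truncated to
#'   the speed range), `"loguniform"` (fields `min`, `max`), or `"point"`
#'   (field `at`). Support must lie within \[1.25, 80\] deg/s.
#' @param seed integer seed; the generator is deterministic given it.
#' @return A data frame of class `"neuron_population"`, one row per neuron:
#'   `id`, `preferred_speed` (deg/s), `tuning_width` (sd of the Gaussian in
#'   ln speed), `peak_rate`, `baseline_rate` (spikes/s), `preferred_direction`
#'   (deg), `direction_concentration` (von Mises kappa).
#' @examples
#' pop <- make_population(100, seed = 1)
#' range(pop$preferred_speed)
#' @export
make_population <- function(n_neurons,
                            pref_dist = list(kind = "lognormal",
                                             meanlog = log(18), sdlog = 1.5),
                            seed = 1L) {
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  rng <- speed_range()
  kind <- match.arg(pref_dist$kind, c("lognormal", "loguniform", "point"))
  set.seed(seed)

  pref <- switch(kind,
    lognormal = {
      lo <- stats::pnorm(log(rng[1]), pref_dist$meanlog, pref_dist$sdlog)
      hi <- stats::pnorm(log(rng[2]), pref_dist$meanlog, pref_dist$sdlog)
      u <- stats::runif(n_neurons, lo, hi)
      exp(stats::qnorm(u, pref_dist$meanlog, pref_dist$sdlog))
    },
    loguniform = {
      if (pref_dist$min < rng[1] || pref_dist$max > rng[2])
        stop("preferred-speed distribution support must lie within [1.25, 80] deg/s")
      exp(stats::runif(n_neurons, log(pref_dist$min), log(pref_dist$max)))
    },
    point = {
      if (pref_dist$at < rng[1] || pref_dist$at > rng[2])
        stop("preferred-speed distribution support must lie within [1.25, 80] deg/s")
      rep(pref_dist$at, n_neurons)
    }
  )

  # ln-domain tuning width ~ 1.45 octaves (the standard MT log-Gaussian fit)
  width <- pmin(pmax(stats::rnorm(n_neurons, 1.0, 0.25), 0.5), 2.0)
  peak <- exp(stats::rnorm(n_neurons, log(45), 0.35))
  base <- stats::runif(n_neurons, 0, pmin(10, 0.4 * peak))
  pop <- data.frame(
    id = sprintf("n%03d", seq_len(n_neurons)),
    preferred_speed = pref,
    tuning_width = width,
    peak_rate = peak,
    baseline_rate = base,
    preferred_direction = stats::runif(n_neurons, 0, 360),
    direction_concentration = stats::runif(n_neurons, 1.5, 4),
    stringsAsFactors = FALSE
  )
  class(pop) <- c("neuron_population", "data.frame")
  pop
}

#' Full stimulus speed range (deg/s)
#' @return numeric vector `c(1.25, 80)`.
#' @export
speed_range <- function() c(1.25, 80)

#' Log-Gaussian speed tuning of a model neuron
#'
#' Response (spikes/s) of one or more model neurons to a single speed:
#' `baseline + (peak - baseline) * exp(-(ln v - ln PS)^2 / (2 width^2))`.
#' The maximum is attained exactly at the preferred speed and the response
#' decays to the baseline at very slow and very fast speeds.
#'
#' @param neuron one row of a `neuron_population` (or the whole population,
#'   in which case a matrix is returned for vector `speed`).
#' @param speed speed(s) in deg/s, must be positive.
#' @return spikes/s; for a population and several speeds, a matrix with one
#'   row per neuron and one column per speed.
#' @export
tuning_response <- function(neuron, speed) {
  if (any(speed <= 0)) stop("speed must be positive")
  neuron <- as.data.frame(neuron)
  d <- outer(log(neuron$preferred_speed), log(speed), "-")  # neurons x speeds
  out <- neuron$baseline_rate + (neuron$peak_rate - neuron$baseline_rate) *
    exp(-d^2 / (2 * neuron$tuning_width^2))
  if (nrow(neuron) == 1L || length(speed) == 1L) as.numeric(out) else out
}

#' Encoding rules for bi-speed responses
#'
#' Constructs the rule that combines a neuron's responses to the two
#' component speeds into its bi-speed response:
#' \describe{
#'   \item{`fixed_weights`}{`R = w_s R_s + w_f R_f` (+ optional offset `c`).}
#'   \item{`average`}{equal weights 1/2.}
#'   \item{`random_weights`}{per-neuron weight `a ~ U(0, 1)` for the faster
#'     component, `R = a R_f + (1 - a) R_s`.}
#'   \item{`lws`}{linear weighted sum with offset, identical in form to
#'     `fixed_weights` with `c` allowed.}
#'   \item{`normalization`}{weighting-pool divisive normalization:
#'     `w_s = S_s^n / (S_s^n + alpha S_f^n + sigma)` and
#'     `w_f = S_f^n / (S_s^n + alpha S_f^n + sigma)`, where `S_s`, `S_f`
#'     are the weighting-pool responses to the two component speeds.}
#' }
#'
#' @param kind one of `"fixed_weights"`, `"average"`, `"random_weights"`,
#'   `"lws"`, `"normalization"`.
#' @param ... rule parameters (`w_s`, `w_f`, `c` for fixed/lws;
#'   `n`, `sigma`, `alpha`, `c`, and optionally `S_s`, `S_f` for
#'   normalization; `seed` for random_weights).
#' @return a list of class `"encoding_rule"`.
#' @export
encoding_rule <- function(kind = c("fixed_weights", "average",
                                   "random_weights", "lws", "normalization"),
                          ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (kind %in% c("fixed_weights", "lws")) {
    if (is.null(pars$w_s) || is.null(pars$w_f))
      stop("fixed_weights/lws rules need w_s and w_f")
    if (is.null(pars$c)) pars$c <- 0
    if (pars$c < 0 || pars$c > 100) stop("offset c must be in [0, 100]")
  }
  if (kind == "normalization") {
    need <- c("n", "sigma", "alpha")
    if (!all(need %in% names(pars)))
      stop("normalization rule needs n, sigma and alpha")
    if (is.null(pars$c)) pars$c <- 0
    if (pars$n < 0.01 || pars$n > 100) stop("n must be in [0.01, 100]")
    if (pars$sigma < 0 || pars$sigma > 500) stop("sigma must be in [0, 500]")
    if (pars$alpha < 0.01 || pars$alpha > 100) stop("alpha must be in [0.01, 100]")
    if (pars$c < 0 || pars$c > 100) stop("offset c must be in [0, 100]")
  }
  structure(list(kind = kind, parameters = pars), class = "encoding_rule")
}

#' Weighting-pool response to a single speed
#'
#' The population-average firing rate of the whole population in response
#' to one speed; used as the pool term `S` in the normalization rule. For a
#' population resembling recorded MT data this curve peaks near 20 deg/s,
#' which is what generates the faster-speed bias at slow speeds.
#'
#' @param population a `neuron_population`.
#' @param speed speed(s), deg/s.
#' @return mean spikes/s across the population, per speed.
#' @export
weighting_pool_response <- function(population, speed) {
  resp <- tuning_response(population, speed)
  if (is.matrix(resp)) colMeans(resp) else mean(resp)
}

#' Trial-averaged bi-speed responses under an encoding rule
#'
#' Computes each neuron's noise-free trial-averaged response to a bi-speed
#' stimulus from its single-speed responses `R_s = f(v_s)`, `R_f = f(v_f)`
#' under the given encoding rule.
#'
#' @param population a `neuron_population`.
#' @param condition a [bispeed_condition()] (or list with `v_s`, `v_f`).
#' @param rule an [encoding_rule()].
#' @return data frame with columns `neuron_id`, `R_s`, `R_f`, `R` (spikes/s)
#'   and, where the rule assigns them, `w_s`, `w_f`.
#' @export
make_bispeed_responses <- function(population, condition, rule) {
  rng <- speed_range()
  if (condition$v_s < rng[1] || condition$v_f > rng[2])
    stop("condition speeds must lie within [1.25, 80] deg/s")
  if (!inherits(rule, "encoding_rule")) stop("rule must be an encoding_rule")
  R_s <- tuning_response(population, condition$v_s)
  R_f <- tuning_response(population, condition$v_f)
  p <- rule$parameters
  n <- nrow(population)
  res <- switch(rule$kind,
    fixed_weights = ,
    lws = {
      w_s <- rep(p$w_s, n); w_f <- rep(p$w_f, n)
      list(R = p$w_s * R_s + p$w_f * R_f + p$c, w_s = w_s, w_f = w_f)
    },
    average = list(R = (R_s + R_f) / 2, w_s = rep(0.5, n), w_f = rep(0.5, n)),
    random_weights = {
      if (!is.null(p$seed)) set.seed(p$seed)
      a <- stats::runif(n)
      list(R = a * R_f + (1 - a) * R_s, w_s = 1 - a, w_f = a)
    },
    normalization = {
      S_s <- if (is.null(p$S_s)) weighting_pool_response(population, condition$v_s) else p$S_s
      S_f <- if (is.null(p$S_f)) weighting_pool_response(population, condition$v_f) else p$S_f
      den <- S_s^p$n + p$alpha * S_f^p$n + p$sigma
      w_s <- rep(S_s^p$n / den, n); w_f <- rep(S_f^p$n / den, n)
      list(R = w_s * R_s + w_f * R_f + p$c, w_s = w_s, w_f = w_f)
    },
    stop("unknown encoding rule kind")
  )
  data.frame(neuron_id = population$id, R_s = R_s, R_f = R_f, R = res$R,
             w_s = res$w_s, w_f = res$w_f, stringsAsFactors = FALSE)
}

#' Poisson spike-count trials from mean rates
#'
#' Spike counts per trial are drawn independently for each neuron and
#' condition from a Poisson distribution with mean `rate * duration`,
#' matching the study's simulated trials (500 ms motion period by default).
#'
#' @param mean_rates data frame with columns `neuron_id`, `condition_id`,
#'   `rate` (spikes/s, >= 0), or a named numeric vector of rates for a
#'   single condition.
#' @param n_trials trials per neuron-condition (>= 1).
#' @param duration trial duration in seconds.
#' @param seed integer seed.
#' @return data frame (TrialTable) with columns `neuron_id`, `condition_id`,
#'   `trial_index`, `spike_count`, `duration`.
#' @export
generate_poisson_trials <- function(mean_rates, n_trials, duration = 0.5,
                                    seed = 1L) {
  if (!is.data.frame(mean_rates)) {
    mean_rates <- data.frame(neuron_id = names(mean_rates),
                             condition_id = "cond1",
                             rate = as.numeric(mean_rates),
                             stringsAsFactors = FALSE)
  }
  if (any(mean_rates$rate < 0)) stop("mean rates must be nonnegative")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  k <- nrow(mean_rates)
  out <- data.frame(
    neuron_id = rep(mean_rates$neuron_id, each = n_trials),
    condition_id = rep(mean_rates$condition_id, each = n_trials),
    trial_index = rep(seq_len(n_trials), k),
    spike_count = stats::rpois(k * n_trials,
                               rep(mean_rates$rate, each = n_trials) * duration),
    duration = duration,
    stringsAsFactors = FALSE
  )
  out
}

#' Synthetic bi-speed / bi-direction tuning set
#'
#' Builds the three direction-tuning curves used by the component-model
#' fits: the neuron's response to the slower component alone, to the
#' faster component alone, and to both presented together, sampled on a
#' uniform vector-average (VA) direction grid. Component directions are
#' offset by `offset` degrees about the VA direction (the faster component
#' on the clockwise side). Each component response is von Mises shaped in
#' direction, scaled by the neuron's speed tuning at that component's
#' speed; the bi-speed curve is the weighted sum
#' `w_s R_s(theta1) + w_f R_f(theta2) + c` (zero-noise by default, with
#' optional iid Gaussian noise).
#'
#' @param neuron one row of a `neuron_population`.
#' @param v_s,v_f component speeds (deg/s).
#' @param w_s,w_f,c generative weights and offset of the bi-speed curve.
#' @param n_directions grid size (default 24, i.e. 15-degree steps).
#' @param offset angular separation of the two components (degrees).
#' @param noise_sd sd of additive Gaussian noise on all three curves.
#' @param seed seed used when `noise_sd > 0`.
#' @return data frame with `va_direction`, `r_slower`, `r_faster`, `r_bi`.
#' @export
make_direction_tuning <- function(neuron, v_s = 2.5, v_f = 10,
                                  w_s = 0.26, w_f = 0.74, c = 0,
                                  n_directions = 24, offset = 90,
                                  noise_sd = 0, seed = 1L) {
  va <- seq(0, 360 - 360 / n_directions, by = 360 / n_directions)
  kappa <- neuron$direction_concentration
  pd <- neuron$preferred_direction
  dirshape <- function(d) exp(kappa * (cos((d - pd) * pi / 180) - 1))
  theta1 <- va + offset / 2   # slower component (counter-clockwise side)
  theta2 <- va - offset / 2   # faster component (clockwise side)
  r_s <- tuning_response(neuron, v_s) * dirshape(theta1)
  r_f <- tuning_response(neuron, v_f) * dirshape(theta2)
  r_bi <- w_s * r_s + w_f * r_f + c
  if (noise_sd > 0) {
    set.seed(seed)
    r_s <- r_s + stats::rnorm(n_directions, 0, noise_sd)
    r_f <- r_f + stats::rnorm(n_directions, 0, noise_sd)
    r_bi <- r_bi + stats::rnorm(n_directions, 0, noise_sd)
  }
  data.frame(va_direction = va, r_slower = r_s, r_faster = r_f, r_bi = r_bi)
}
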