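#' The 121-point log-uniform speed grid
#'
#' Speeds from 1.25 to 80 deg/s, evenly spaced in natural log with 121
#' values (step (ln 80 - ln 1.25)/120 = 0.0347). This grid is the speed
#' axis of the decoder: candidate speeds, speed separations and the
#' evaluation sites of all population splines live on it.
#'
#' @param n number of grid points (default 121; reduced grids are useful
#'   for exhaustive-search cross-checks).
#' @return list of class `"speed_grid"`: `speeds` (deg/s), `ln_speeds`,
#'   `log_step`, `n`.
#' @export
build_speed_grid <- function(n = 121L) {
  rng <- speed_range()
  ln <- seq(log(rng[1]), log(rng[2]), length.out = n)
  structure(list(speeds = exp(ln), ln_speeds = ln,
                 log_step = (log(rng[2]) - log(rng[1])) / (n - 1), n = n),
            class = "speed_grid")
}

#' Smoothing-spline fit of a speed tuning curve
#'
#' Fits the trial-averaged responses to single speeds with a cubic
#' smoothing spline on the natural-log speed axis (smoothing parameter
#' `p = 0.93`, see [csaps_fit()]), and extracts the preferred speed (the
#' argmax of the fitted curve over a dense 1201-point log-uniform grid
#' within the full speed range; ties are broken to the slowest maximizer)
#' and the maximum rate of the fitted curve, which is the normalization
#' divisor for all of the neuron's responses.
#'
#' @param speeds stimulus speeds (deg/s), at least 4 distinct values.
#' @param rates trial-averaged responses (spikes/s).
#' @param p smoothing parameter (default 0.93).
#' @return list of class `"speed_tuning"`: `speeds`, `rates`, `spline`
#'   (a `"csaps"` object over ln speed), `preferred_speed`, `max_rate`,
#'   `tie_flag` (TRUE when the fitted curve is flat to within 1e-12).
#' @export
fit_tuning_curve <- function(speeds, rates, p = 0.93) {
  if (length(unique(speeds)) < 4) stop("need at least 4 distinct speeds")
  if (any(!is.finite(rates))) stop("rates must be finite")
  sp <- csaps_fit(log(speeds), rates, p = p)
  dense <- seq(log(speed_range()[1]), log(speed_range()[2]), length.out = 1201)
  vals <- predict(sp, dense)
  tie <- (max(vals) - min(vals)) < 1e-12
  structure(list(speeds = speeds, rates = rates, spline = sp,
                 preferred_speed = exp(dense[which.max(vals)]),
                 max_rate = max(vals), tie_flag = tie),
            class = "speed_tuning")
}

#' Preferred speed of a fitted tuning curve
#' @param curve a `"speed_tuning"` object from [fit_tuning_curve()].
#' @return deg/s.
#' @export
preferred_speed <- function(curve) curve$preferred_speed

#' Fit tuning curves for every neuron of a population
#'
#' Convenience wrapper: evaluates each model neuron's (noise-free or
#' trial-averaged) responses to the single study speeds and fits the
#' smoothing-spline tuning curve per neuron.
#'
#' @param population a `neuron_population`.
#' @param speeds single speeds to probe (default [study_speeds()]).
#' @param rates optional matrix (neurons x speeds) of trial-averaged
#'   responses; when missing, noise-free tuning responses are used.
#' @param p smoothing parameter.
#' @return list of class `"tuning_set"`: per-neuron `"speed_tuning"`
#'   fits (named by neuron id), plus `ids`.
#' @export
fit_tuning_set <- function(population, speeds = study_speeds(), rates = NULL,
                           p = 0.93) {
  if (is.null(rates)) rates <- tuning_response(population, speeds)
  curves <- lapply(seq_len(nrow(population)), function(i)
    fit_tuning_curve(speeds, rates[i, ], p = p))
  names(curves) <- population$id
  structure(list(curves = curves, ids = population$id), class = "tuning_set")
}

#' Normalized pseudo-population response to one stimulus
#'
#' Pools the responses of separately characterized neurons to a common
#' stimulus into one population response: each neuron's rate is divided by
#' the maximum of its spline-fitted single-speed tuning curve, plotted
#' against the neuron's ln preferred speed, and smoothed with a `p = 0.93`
#' spline evaluated on the 121-point speed grid. Neurons with a
#' non-positive fitted maximum, or missing a response to the stimulus, are
#' excluded (with a warning for the latter).
#'
#' @param tuning a `"tuning_set"` from [fit_tuning_set()].
#' @param responses named numeric vector: trial-averaged response
#'   (spikes/s) of each neuron to the stimulus; names are neuron ids.
#' @param grid a `"speed_grid"` (default the 121-point grid).
#' @param p smoothing parameter for the population spline.
#' @return list of class `"population_response"`: `neuron_ids`,
#'   `ln_preferred_speeds`, `normalized_responses`, `grid`,
#'   `spline_values` (one per grid point).
#' @export
build_pseudopopulation <- function(tuning, responses,
                                   grid = build_speed_grid(), p = 0.93) {
  ids <- tuning$ids
  missing_ids <- setdiff(ids, names(responses))
  if (length(missing_ids) > 0)
    warning("excluding neurons without a response to the condition: ",
            paste(missing_ids, collapse = ", "))
  ids <- intersect(ids, names(responses))
  maxr <- vapply(tuning$curves[ids], function(cu) cu$max_rate, numeric(1))
  ids <- ids[maxr > 0]
  if (length(ids) < 1) stop("no usable neurons")
  lnps <- vapply(tuning$curves[ids], function(cu) log(cu$preferred_speed),
                 numeric(1))
  norm <- as.numeric(responses[ids]) /
    vapply(tuning$curves[ids], function(cu) cu$max_rate, numeric(1))
  ord <- order(lnps)
  ids <- ids[ord]; lnps <- lnps[ord]; norm <- norm[ord]
  # neurons sharing a preferred speed contribute one weighted knot
  ux <- unique(lnps)
  if (length(ux) == 1L) {
    # degenerate population: flat curve at the common normalized value
    return(structure(list(neuron_ids = ids, ln_preferred_speeds = lnps,
                          normalized_responses = norm, grid = grid,
                          spline_values = rep(mean(norm), grid$n)),
                     class = "population_response"))
  }
  if (length(ux) < length(lnps)) {
    g <- match(lnps, ux)
    uy <- as.numeric(tapply(norm, g, mean))
    uw <- as.numeric(table(g))
    sp <- csaps_fit(ux, uy, p = p, w = uw)
  } else {
    sp <- csaps_fit(lnps, norm, p = p)
  }
  structure(list(neuron_ids = ids, ln_preferred_speeds = lnps,
                 normalized_responses = norm, grid = grid,
                 spline_values = predict(sp, grid$ln_speeds),
                 # normalized responses may exceed 1 slightly because the
                 # smoothed tuning maximum undershoots a sharp peak; values
                 # beyond 1.10 are flagged for inspection
                 flagged = ids[norm > 1.10]),
            class = "population_response")
}

#' @export
plot.population_response <- function(x, ...) {
  plot(x$ln_preferred_speeds, x$normalized_responses,
       xlab = "ln preferred speed", ylab = "normalized response",
       pch = 16, col = "grey40", ...)
  graphics::lines(x$grid$ln_speeds, x$spline_values, col = "red", lwd = 2)
  invisible(x)
}
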