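#' Speed probability distribution on the grid
#'
#' A distribution over the decoder's speed grid constrained to at most two
#' support points with probabilities summing to one.
#'
#' @param support_indices 1 or 2 grid indices (1-based).
#' @param probabilities probabilities per support point, nonnegative,
#'   summing to 1.
#' @param grid the `"speed_grid"` the indices refer to.
#' @return list of class `"speed_distribution"`.
#' @export
speed_distribution <- function(support_indices, probabilities,
                               grid = build_speed_grid()) {
  if (length(support_indices) != length(probabilities) ||
      !length(support_indices) %in% 1:2)
    stop("need 1 or 2 support points with matching probabilities")
  if (any(support_indices < 1) || any(support_indices > grid$n) ||
      any(support_indices != round(support_indices)))
    stop("support index off-grid")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-12)
    stop("probabilities must be nonnegative and sum to 1")
  structure(list(support_indices = as.integer(support_indices),
                 probabilities = probabilities, grid = grid),
            class = "speed_distribution")
}

#' Estimated response of one neuron to a speed distribution
#'
#' The forward encoding rule of the decoder: the neuron's normalized
#' response to a speed distribution is the probability-weighted sum of its
#' normalized spline-fitted tuning curve at the support speeds,
#' `ES_i = sum_j P_j f_i(S_j)`.
#'
#' @param curve a `"speed_tuning"` fit ([fit_tuning_curve()]).
#' @param distribution a [speed_distribution()].
#' @return normalized response (dimensionless).
#' @export
estimate_component_response <- function(curve, distribution) {
  lnv <- distribution$grid$ln_speeds[distribution$support_indices]
  sum(distribution$probabilities * predict(curve$spline, lnv)) / curve$max_rate
}

#' Precompute the decoder's linear machinery for a population
#'
#' Builds, once per population, everything the decoder's grid search
#' needs: the normalized tuning matrix `FS` (neurons x grid speeds), the
#' population smoothing operator `H` (grid x knots, the `p = 0.93`
#' smoothing spline over ln preferred speed as a linear map), and their
#' product `G = H FS` whose column `j` is the spline-fitted estimated
#' population response to a point mass at grid speed `j`. For any
#' candidate distribution the estimated response `spEP` is then just a
#' convex combination of two columns of `G`, so each candidate costs a
#' few dot products. Neurons sharing a preferred speed are merged into one
#' weighted spline knot.
#'
#' @param tuning a `"tuning_set"` ([fit_tuning_set()]).
#' @param grid evaluation grid (default 121 points).
#' @param p smoothing parameter of the population spline.
#' @return list of class `"decoder_setup"`.
#' @export
decoder_setup <- function(tuning, grid = build_speed_grid(), p = 0.93) {
  ids <- tuning$ids
  maxr <- vapply(tuning$curves, function(cu) cu$max_rate, numeric(1))
  keep <- maxr > 0
  ids <- ids[keep]
  curves <- tuning$curves[ids]
  maxr <- maxr[keep]
  lnps <- vapply(curves, function(cu) log(cu$preferred_speed), numeric(1))
  FS <- t(vapply(seq_along(curves), function(i)
    predict(curves[[i]]$spline, grid$ln_speeds) / maxr[i],
    numeric(grid$n)))                       # neurons x grid speeds

  ux <- sort(unique(lnps))
  gidx <- match(lnps, ux)
  nk <- as.numeric(table(gidx))
  Agg <- matrix(0, length(ux), length(ids))  # knot-averaging of neurons
  Agg[cbind(gidx, seq_along(ids))] <- 1 / nk[gidx]
  H <- csaps_operator(ux, p = p, xout = grid$ln_speeds, w = nk)
  HA <- H %*% Agg                            # responses -> spline on grid
  G <- HA %*% FS                             # point-mass spEP per grid speed
  structure(list(ids = ids, ln_preferred_speeds = lnps, max_rates = maxr,
                 grid = grid, FS = FS, HA = HA, G = G, GG = crossprod(G),
                 p = p),
            class = "decoder_setup")
}

#' Spline-fitted recorded population response from neuron responses
#'
#' @param setup a `"decoder_setup"`.
#' @param responses spikes/s per neuron, named by or ordered as
#'   `setup$ids`.
#' @return `spRP`, the normalized, spline-fitted population response on
#'   the grid.
#' @export
population_spline <- function(setup, responses) {
  if (!is.null(names(responses))) responses <- responses[setup$ids]
  as.numeric(setup$HA %*% (responses / setup$max_rates))
}

#' Spline-fitted estimated population response to a distribution
#'
#' `spEP` for an admissible distribution: the probability-weighted
#' combination of the point-mass columns of `G`.
#'
#' @inheritParams population_spline
#' @param distribution a [speed_distribution()].
#' @return numeric vector on the grid.
#' @export
estimate_population <- function(setup, distribution) {
  as.numeric(setup$G[, distribution$support_indices, drop = FALSE] %*%
               distribution$probabilities)
}

#' Decoder objective: negative sum of squared differences
#'
#' @param spEP,spRP estimated and recorded spline-fitted population
#'   responses on the same grid.
#' @return `-sum((spEP - spRP)^2)`, always <= 0, 0 iff the curves match.
#' @export
decode_objective <- function(spEP, spRP) {
  if (length(spEP) != length(spRP)) stop("grid mismatch")
  -sum((spEP - spRP)^2)
}

#' Search configuration for the two-speed decoder
#'
#' Defaults follow the full 121-point grid: speed separations from 2 to 96
#' grid steps (speed ratios 1.07x to 27.86x) in steps of 2, probabilities
#' on a 0.01 lattice, hill-climbing continuation of 30 intervals past a
#' local maximum, and the 0.7 weight-gap rule for calling a readout
#' single.
#'
#' @param separation_min_steps,separation_max_steps,separation_step even
#'   grid-step counts defining the searched separations.
#' @param probability_step lattice step for the two weights.
#' @param continuation_intervals how far past a local maximum the center
#'   walk keeps looking for a larger objective.
#' @param single_readout_weight_gap gap above which a two-speed readout is
#'   classified as single.
#' @param weight_mode `"scan"` evaluates the whole probability lattice as
#'   specified; `"quadratic"` minimizes the (exactly quadratic) SSE in the
#'   weight analytically and rounds to the lattice -- same optimum, faster.
#' @return list of class `"search_config"`.
#' @export
search_config <- function(separation_min_steps = 2L,
                          separation_max_steps = 96L,
                          separation_step = 2L,
                          probability_step = 0.01,
                          continuation_intervals = 30L,
                          single_readout_weight_gap = 0.7,
                          weight_mode = c("scan", "quadratic")) {
  if (separation_min_steps %% 2 != 0 || separation_step %% 2 != 0)
    stop("separations must be even grid-step counts (centers lie on the grid)")
  structure(list(separation_min_steps = as.integer(separation_min_steps),
                 separation_max_steps = as.integer(separation_max_steps),
                 separation_step = as.integer(separation_step),
                 probability_step = probability_step,
                 continuation_intervals = as.integer(continuation_intervals),
                 single_readout_weight_gap = single_readout_weight_gap,
                 weight_mode = match.arg(weight_mode)),
            class = "search_config")
}

#' Classify a decoded readout as single or two speeds
#'
#' A readout with one support point, or whose two weights differ by
#' strictly more than the gap (default 0.7, i.e. the weaker weight below
#' 0.15), is classified `"single"`; otherwise `"two"`. A gap of exactly
#' 0.7 is `"two"` (strict inequality).
#'
#' @param weights 1 or 2 probabilities summing to 1.
#' @param gap weight-difference threshold.
#' @return `"single"` or `"two"`.
#' @export
classify_readout <- function(weights, gap = 0.7) {
  if (length(weights) == 1L) return("single")
  if (abs(weights[1] - weights[2]) > gap) "single" else "two"
}

#' Decode one or two speeds from a population response
#'
#' Finds the admissible speed distribution (one support point, or two
#' support points with lattice weights summing to one) whose estimated
#' population response best matches `spRP` under the negative-SSE
#' objective. Stage 1 searches all single grid speeds exhaustively. Stage
#' 2, for each searched separation, hill-climbs the pair's center position
#' from the middle of the speed axis toward each border: the walk moves
#' while the objective improves, and after a local maximum keeps probing
#' up to `continuation_intervals` further steps, jumping there if a larger
#' objective appears; it stops at a border or when the continuation is
#' exhausted. At every (separation, center) the two weights are optimized
#' on the probability lattice. The better of the single- and two-speed
#' optima is returned (an exact tie prefers the single-speed solution and
#' sets `tie_flag`).
#'
#' @param setup a `"decoder_setup"`.
#' @param spRP recorded spline-fitted population response on the grid
#'   (see [population_spline()]); alternatively give `responses`.
#' @param responses named spikes/s per neuron, used when `spRP` is NULL.
#' @param config a [search_config()].
#' @return list of class `"decode_result"`: `readout_speeds` (deg/s),
#'   `weights`, `objective`, `readout_class`, `boundary_flags`,
#'   `estimated_population`, `of_single`, `of_two`, `tie_flag`.
#' @export
decode <- function(setup, spRP = NULL, responses = NULL,
                   config = search_config()) {
  if (is.null(spRP)) {
    if (is.null(responses)) stop("give spRP or responses")
    spRP <- population_spline(setup, responses)
  }
  n <- setup$grid$n
  if (length(spRP) != n) stop("spRP must be on the decoder grid")
  G <- setup$G; GG <- setup$GG
  gg <- diag(GG)
  Gy <- as.numeric(crossprod(G, spRP))
  yy <- sum(spRP^2)

  # stage 1: exhaustive single-speed search
  sse1 <- gg - 2 * Gy + yy
  j1 <- which.min(sse1)        # ties break to the slowest grid speed
  of1 <- -sse1[j1]

  # weight optimization at one (separation, center): SSE is quadratic in w
  wlat <- seq(0, 1, by = config$probability_step)
  pair_opt <- function(jlo, jhi) {
    A <- gg[jlo] - 2 * GG[jlo, jhi] + gg[jhi]
    B <- GG[jlo, jhi] - gg[jhi] - Gy[jlo] + Gy[jhi]
    C <- gg[jhi] - 2 * Gy[jhi] + yy
    if (config$weight_mode == "scan") {
      sse <- wlat^2 * A + 2 * wlat * B + C
      i <- which.min(sse)
      c(of = -sse[i], w = wlat[i])
    } else {
      wstar <- if (A > 0) min(max(-B / A, 0), 1) else 0
      cand <- unique(pmin(pmax(
        c(floor(wstar / config$probability_step),
          ceiling(wstar / config$probability_step)) * config$probability_step,
        0), 1))
      sse <- cand^2 * A + 2 * cand * B + C
      # on an exact tie keep the smaller weight, as the lattice scan does
      i <- which.min(sse)
      c(of = -sse[i], w = cand[i])
    }
  }

  seps <- seq(config$separation_min_steps,
              min(config$separation_max_steps, n - 1),
              by = config$separation_step)
  seps <- seps[seps %% 2 == 0 & seps >= 2]
  j0 <- (n + 1L) %/% 2L        # middle of the speed axis
  best2 <- list(of = -Inf, center = NA, k = NA, w = NA)

  for (s in seps) {
    k <- s %/% 2L
    valid <- function(j) (j - k) >= 1L && (j + k) <= n
    if (!valid(j0)) next
    cache <- rep(NA_real_, n)
    wcache <- rep(NA_real_, n)
    of_at <- function(j) {
      if (is.na(cache[j])) {
        r <- pair_opt(j - k, j + k)
        cache[j] <<- r["of"]; wcache[j] <<- r["w"]
      }
      cache[j]
    }
    for (dir in c(-1L, 1L)) {
      j <- j0
      cur <- of_at(j)
      repeat {
        # greedy walk while the neighbor improves
        repeat {
          jn <- j + dir
          if (!valid(jn)) { jn <- NA; break }
          on <- of_at(jn)
          if (on > cur) { j <- jn; cur <- on } else break
        }
        if (is.na(jn)) break   # component speed hit a border
        # local maximum: continue up to `continuation_intervals` further
        jumped <- FALSE
        for (m in seq_len(config$continuation_intervals)) {
          jc <- j + dir * m
          if (!valid(jc)) break
          if (of_at(jc) > cur) { j <- jc; cur <- of_at(jc); jumped <- TRUE; break }
        }
        if (!jumped) break
      }
      if (cur > best2$of)
        best2 <- list(of = cur, center = j, k = k, w = wcache[j])
    }
  }

  tie <- is.finite(best2$of) && best2$of == of1
  if (of1 >= best2$of) {
    dist <- speed_distribution(j1, 1, setup$grid)
    speeds <- setup$grid$speeds[j1]
    weights <- 1
    flags <- FALSE   # a full-weight readout is never a boundary artifact
  } else {
    jlo <- best2$center - best2$k
    jhi <- best2$center + best2$k
    w <- best2$w
    dist <- speed_distribution(c(jlo, jhi), c(w, 1 - w), setup$grid)
    speeds <- setup$grid$speeds[c(jlo, jhi)]
    weights <- c(w, 1 - w)
    max_sep <- max(seps)
    at_edge <- c(jlo == 1L, jhi == n) | (jhi - jlo) == max_sep
    flags <- at_edge & (weights < 0.15)
  }
  structure(list(readout_speeds = speeds, weights = weights,
                 objective = max(of1, best2$of),
                 readout_class = classify_readout(
                   weights, config$single_readout_weight_gap),
                 boundary_flags = flags,
                 estimated_population = estimate_population(setup, dist),
                 of_single = of1, of_two = best2$of, tie_flag = tie),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Decoded %s-speed readout: %s deg/s (weights %s), OF = %.4g\n",
              x$readout_class,
              paste(signif(x$readout_speeds, 4), collapse = ", "),
              paste(signif(x$weights, 3), collapse = ", "),
              x$objective))
  invisible(x)
}

#' Decode Poisson-resampled trials
#'
#' Generates `n_trials` Poisson spike-count trials around the given mean
#' rates (500 ms window by default), normalizes and spline-fits each
#' trial's population response, and decodes it.
#'
#' @param setup a `"decoder_setup"`.
#' @param rates mean spikes/s per neuron (named by or ordered as
#'   `setup$ids`).
#' @param n_trials trials to generate.
#' @param duration seconds per trial.
#' @param seed integer seed.
#' @param config a [search_config()].
#' @return data frame with one row per trial: `trial`, `readout_class`,
#'   `v1`, `v2` (NA for single readouts), `w1`, `w2`, `ln_separation`,
#'   `objective`; the full `decode_result` objects are attached as
#'   attribute `"decodes"`.
#' @export
decode_trials <- function(setup, rates, n_trials = 200, duration = 0.5,
                          seed = 1L, config = search_config()) {
  if (!is.null(names(rates))) rates <- rates[setup$ids]
  set.seed(seed)
  counts <- matrix(stats::rpois(n_trials * length(rates),
                                rep(rates, each = n_trials) * duration),
                   nrow = n_trials)
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    y <- stats::setNames(counts[t, ] / duration, setup$ids)
    out[[t]] <- decode(setup, spRP = population_spline(setup, y),
                       config = config)
  }
  df <- data.frame(
    trial = seq_len(n_trials),
    readout_class = vapply(out, function(d) d$readout_class, character(1)),
    v1 = vapply(out, function(d) d$readout_speeds[1], numeric(1)),
    v2 = vapply(out, function(d)
      if (length(d$readout_speeds) > 1) d$readout_speeds[2] else NA_real_,
      numeric(1)),
    w1 = vapply(out, function(d) d$weights[1], numeric(1)),
    w2 = vapply(out, function(d)
      if (length(d$weights) > 1) d$weights[2] else NA_real_, numeric(1)),
    ln_separation = vapply(out, decode_separation, numeric(1)),
    objective = vapply(out, function(d) d$objective, numeric(1))
  )
  attr(df, "decodes") <- out
  df
}

#' Log speed separation of a decode result
#'
#' `|ln v2 - ln v1|` for a two-class readout, 0 for a single-class one
#' (the convention used by the decode-based discrimination).
#'
#' @param decode_result a `"decode_result"`.
#' @return nonnegative log-ratio.
#' @export
decode_separation <- function(decode_result) {
  if (decode_result$readout_class == "single" ||
      length(decode_result$readout_speeds) < 2) return(0)
  abs(diff(log(decode_result$readout_speeds)))
}

#' Discriminate bi-speed from single-speed stimuli via decoded separations
#'
#' A trial counts as a "two speeds" report when its decoded log speed
#' separation exceeds `ln(threshold_ratio)` (default 1.3x, i.e. 0.26 in
#' log units). Hits are bi-speed trials reported as two speeds; false
#' alarms are single-speed trials reported as two speeds; d-prime uses the
#' modified formula at extreme rates.
#'
#' @param decodes_bi,decodes_single lists of `"decode_result"` objects (or
#'   data frames from [decode_trials()], whose `ln_separation` column is
#'   used).
#' @param threshold_ratio speed-ratio threshold (default 1.3).
#' @return list: `hit_rate`, `false_alarm_rate`, `d_prime`, `threshold_ratio`.
#' @export
discriminate_from_decodes <- function(decodes_bi, decodes_single,
                                      threshold_ratio = 1.3) {
  seps <- function(d) {
    if (is.data.frame(d)) return(d$ln_separation)
    vapply(d, decode_separation, numeric(1))
  }
  sb <- seps(decodes_bi)
  ss <- seps(decodes_single)
  if (length(sb) == 0 || length(ss) == 0) stop("decode sets must be nonempty")
  thr <- log(threshold_ratio)
  hit <- mean(sb > thr)
  fa <- mean(ss > thr)
  list(hit_rate = hit, false_alarm_rate = fa,
       d_prime = dprime(hit, fa), threshold_ratio = threshold_ratio)
}
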