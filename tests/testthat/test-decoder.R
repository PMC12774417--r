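test_that("speed distributions are validated", {
  g <- build_speed_grid()
  expect_error(speed_distribution(c(1, 2, 3), c(0.3, 0.3, 0.4), g), "1 or 2")
  expect_error(speed_distribution(200, 1, g), "off-grid")
  expect_error(speed_distribution(c(1, 5), c(0.6, 0.6), g), "sum to 1")
  d <- speed_distribution(c(31, 61), c(0.8, 0.2), g)
  expect_s3_class(d, "speed_distribution")
})

test_that("estimated component responses are probability-weighted tuning values", {
  tun <- fixture_tuning()
  cu <- tun$curves[[5]]
  g <- build_speed_grid()
  f <- function(j) predict(cu$spline, g$ln_speeds[j]) / cu$max_rate
  # point mass
  expect_equal(estimate_component_response(cu, speed_distribution(41, 1, g)),
               f(41))
  # equal mixture
  expect_equal(
    estimate_component_response(cu, speed_distribution(c(31, 71), c(0.5, 0.5), g)),
    (f(31) + f(71)) / 2)
  # 0.8/0.2 mixture over 2.5 and 10 deg/s
  i2.5 <- 21; i10 <- 61
  expect_equal(
    estimate_component_response(cu,
      speed_distribution(c(i2.5, i10), c(0.8, 0.2), g)),
    0.8 * f(i2.5) + 0.2 * f(i10))
})

test_that("the objective is the negative sum of squared differences", {
  x <- rnorm(121)
  expect_equal(decode_objective(x, x), 0)
  expect_equal(decode_objective(x + 0.5, x), -121 * 0.25)
  y <- rnorm(121)
  acc <- 0; for (j in 1:121) acc <- acc + (x[j] - y[j])^2  # summation oracle
  expect_equal(decode_objective(x, y), -acc)
  expect_error(decode_objective(x, y[-1]), "grid mismatch")
})

test_that("readouts classify by the 0.7 weight-gap rule", {
  expect_equal(classify_readout(1), "single")
  expect_equal(classify_readout(c(0.5, 0.5)), "two")
  expect_equal(classify_readout(c(0.9, 0.1)), "single")
  expect_equal(classify_readout(c(0.85, 0.15)), "two")  # gap exactly 0.7
})

test_that("decoding a forward-model response recovers the distribution with objective zero", {
  setup <- fixture_decoder()
  g <- setup$grid
  # single speed at the grid midpoint (10 deg/s)
  r <- decode(setup, estimate_population(setup, speed_distribution(61, 1, g)))
  expect_lte(abs(log(r$readout_speeds[which.max(r$weights)] / 10)),
             g$log_step + 1e-9)
  expect_gt(r$objective, -1e-10)
  expect_equal(sum(r$weights), 1, tolerance = 1e-12)

  # 4x-separated pair away from the boundaries (5 and 20 deg/s)
  d <- speed_distribution(c(41, 81), c(0.5, 0.5), g)
  r <- decode(setup, estimate_population(setup, d))
  expect_equal(r$readout_class, "two")
  expect_lte(abs(log(r$readout_speeds[1] / 5)), g$log_step + 1e-9)
  expect_lte(abs(log(r$readout_speeds[2] / 20)), g$log_step + 1e-9)
  expect_gt(r$objective, -1e-10)
  expect_false(any(r$boundary_flags))
  # the recovered estimate matches the input population response
  expect_equal(r$estimated_population, estimate_population(setup, d),
               tolerance = 1e-6)
})

test_that("decoder self-consistency holds for distributions in the two-readout regime", {
  # weights are drawn from [0.15, 0.85]: when the minor weight falls
  # below the single-readout threshold the solution enters the
  # boundary-artifact regime, where the center hill-climb is not
  # guaranteed to reach the global optimum
  setup <- fixture_decoder()
  g <- setup$grid
  set.seed(9)
  for (i in 1:6) {
    k <- sample(1:48, 1)
    ctr <- sample((k + 1):(121 - k), 1)
    w <- sample(seq(0.15, 0.85, by = 0.01), 1)
    d <- speed_distribution(c(ctr - k, ctr + k), c(w, 1 - w), g)
    spRP <- estimate_population(setup, d)
    r <- decode(setup, spRP)
    expect_gt(r$objective, -1e-9)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_lt(max(abs(r$estimated_population - spRP)), 1e-4)
  }
})

test_that("on a reduced grid the search equals brute-force enumeration", {
  pop <- make_population(40, seed = 6)
  tun <- fit_tuning_set(pop)
  g13 <- build_speed_grid(13L)
  setup <- decoder_setup(tun, grid = g13)
  cfg <- search_config(separation_max_steps = 12L, probability_step = 0.1)
  set.seed(21)
  for (i in 1:8) {
    # mix of forward-model and perturbed targets
    k <- sample(1:6, 1); ctr <- sample((k + 1):(13 - k), 1)
    d <- speed_distribution(c(ctr - k, ctr + k), c(0.3, 0.7), g13)
    spRP <- estimate_population(setup, d) + rnorm(13, 0, 0.05 * (i %% 2))
    r <- decode(setup, spRP, config = cfg)
    bf <- brute_force_decode(setup, spRP, sep_max = 12, prob_step = 0.1)
    expect_equal(r$objective, bf$of, tolerance = 1e-12)
  }
})

test_that("analytic weight optimization matches the lattice scan", {
  setup <- fixture_decoder()
  g <- setup$grid
  set.seed(13)
  for (i in 1:4) {
    spRP <- estimate_population(setup,
      speed_distribution(c(31, 71), c(0.4, 0.6), g)) + rnorm(121, 0, 0.03)
    r_scan <- decode(setup, spRP, config = search_config(weight_mode = "scan"))
    r_quad <- decode(setup, spRP,
                     config = search_config(weight_mode = "quadratic"))
    expect_equal(r_scan$objective, r_quad$objective, tolerance = 1e-10)
  }
})

test_that("trial decoding is deterministic and reports separations", {
  setup <- fixture_decoder()
  pop <- fixture_population()
  rates <- stats::setNames(tuning_response(pop, 10), pop$id)
  a <- decode_trials(setup, rates, n_trials = 5, seed = 3)
  b <- decode_trials(setup, rates, n_trials = 5, seed = 3)
  expect_identical(a$objective, b$objective)
  expect_true(all(a$ln_separation >= 0))
  expect_true(all(a$readout_class %in% c("single", "two")))
})

test_that("decode-based discrimination counts hits and false alarms by the 1.3x threshold", {
  mk <- function(class, v1, v2 = NA, w = c(0.5, 0.5)) {
    structure(list(readout_speeds = if (is.na(v2)) v1 else c(v1, v2),
                   weights = if (is.na(v2)) 1 else w,
                   readout_class = class), class = "decode_result")
  }
  bi <- list(mk("two", 5, 20), mk("two", 4, 18), mk("two", 5, 21))
  single <- list(mk("single", 10), mk("single", 9), mk("single", 11))
  r <- discriminate_from_decodes(bi, single)
  expect_equal(r$hit_rate, 1)
  expect_equal(r$false_alarm_rate, 0)
  expect_equal(r$d_prime, 2 * qnorm(101 / 102))
  # identical decode distributions give d-prime 0
  r0 <- discriminate_from_decodes(bi, bi)
  expect_equal(r0$d_prime, 0)
  # thresholds from 1.1x to 1.7x leave these conclusions unchanged
  for (thr in c(1.1, 1.3, 1.7)) {
    rt <- discriminate_from_decodes(bi, single, threshold_ratio = thr)
    expect_equal(rt$hit_rate, 1)
    expect_equal(rt$false_alarm_rate, 0)
  }
  expect_error(discriminate_from_decodes(list(), single), "nonempty")
})
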