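test_that("log-mean speed is the geometric mean", {
  expect_equal(round(log_mean_speed(2.5, 5), 2), 3.54)
  expect_equal(round(log_mean_speed(5, 10), 2), 7.07)
  expect_equal(round(log_mean_speed(10, 20), 2), 14.14)
  expect_equal(round(log_mean_speed(20, 40), 2), 28.28)
  expect_equal(log_mean_speed(1.25, 5), 2.5)
  expect_equal(log_mean_speed(7, 7), 7)
  expect_error(log_mean_speed(-1, 5), "positive")
})

test_that("per-neuron component weights close to one and flag undefined cases", {
  # bi-speed equal to the faster component
  w <- component_weights(R = 60, R_s = 20, R_f = 60)
  expect_equal(c(w$w_s, w$w_f), c(0, 1))
  # midpoint
  w <- component_weights(R = 40, R_s = 20, R_f = 60)
  expect_equal(c(w$w_s, w$w_f), c(0.5, 0.5))
  # direct evaluation
  w <- component_weights(R = 30, R_s = 20, R_f = 60)
  expect_equal(c(w$w_s, w$w_f), c(0.75, 0.25))
  # closure on arbitrary inputs
  set.seed(3)
  R_s <- runif(50, 0, 50); R_f <- runif(50, 0, 50); R <- runif(50, 0, 50)
  w <- component_weights(R, R_s, R_f)
  expect_true(all(abs(w$w_s[w$defined] + w$w_f[w$defined] - 1) < 1e-12))
  # undefined when components are equal
  w <- component_weights(R = 10, R_s = 30, R_f = 30)
  expect_false(w$defined)
  expect_true(is.na(w$w_f))
})

test_that("weight regression matches closed-form OLS and recovers generative weights", {
  # hand-checkable records
  R <- c(10, 20, 12); R_s <- c(5, 10, 10); R_f <- c(15, 30, 14)
  fit <- suppressWarnings(estimate_weights_regression(R, R_s, R_f))
  oracle <- ols_oracle(R_f - R_s, R - R_s)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-12)

  pop <- fixture_population()
  cond <- bispeed_condition(1.25, 5)
  # perfect faster-take-all: slope 1, intercept 0, R^2 = 1
  fta <- make_bispeed_responses(pop, cond, encoding_rule("fixed_weights",
                                                         w_s = 0, w_f = 1))
  fit <- suppressWarnings(estimate_weights_regression(fta$R, fta$R_s, fta$R_f))
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # generic fixed weights are recovered exactly on noise-free data
  for (wf in c(0.25, 0.5, 0.83)) {
    resp <- make_bispeed_responses(pop, cond,
      encoding_rule("fixed_weights", w_s = 1 - wf, w_f = wf))
    fit <- suppressWarnings(
      estimate_weights_regression(resp$R, resp$R_s, resp$R_f))
    expect_lt(abs(fit$slope - wf), 1e-9)
    expect_lt(abs(fit$intercept), 1e-9)
  }
  expect_error(estimate_weights_regression(1:2, 1:2, 2:3), "at least 3")
  expect_error(estimate_weights_regression(1:5, rep(1, 5), rep(2, 5)),
               "degenerate")
})

test_that("random-weight control is unbiased at 0.5 and honors forced weights", {
  pop <- fixture_population()
  cond <- bispeed_condition(2.5, 10)
  resp <- make_bispeed_responses(pop, cond, encoding_rule("average"))
  ctrl <- random_weight_control(resp$R_s, resp$R_f, n_reps = 1000, seed = 11)
  expect_gt(ctrl$mean_slope, 0.45)
  expect_lt(ctrl$mean_slope, 0.55)
  expect_equal(length(ctrl$slopes), 1000)
  # the simulated CI brackets the mean
  expect_gt(ctrl$mean_slope, ctrl$ci95_slope[1])
  expect_lt(ctrl$mean_slope, ctrl$ci95_slope[2])

  # degenerate draws collapse the control to a fixed slope
  all1 <- random_weight_control(resp$R_s, resp$R_f, n_reps = 5, seed = 1,
                                a_sampler = function(n) rep(1, n))
  expect_true(all(abs(all1$slopes - 1) < 1e-9))
  a03 <- random_weight_control(resp$R_s, resp$R_f, n_reps = 5, seed = 1,
                               a_sampler = function(n) rep(0.3, n))
  expect_true(all(abs(a03$slopes - 0.3) < 1e-9))
})

test_that("bootstrap comparison gives order-statistic p-values", {
  sims <- seq(0.3, 0.7, length.out = 1000)
  expect_lt(bootstrap_compare(0.9, sims), 0.001)    # above all simulations
  expect_gt(bootstrap_compare(0.1, sims), 0.999)    # below all simulations
  expect_equal(bootstrap_compare(median(sims), sims), 0.5, tolerance = 0.01)
  expect_error(bootstrap_compare(0.5, numeric(0)), "at least one")
})

test_that("split-trial regression removes the shared term and converges to the all-trials slope", {
  pop <- make_population(60, seed = 5)
  cond <- bispeed_condition(2.5, 10)
  resp <- make_bispeed_responses(pop, cond,
    encoding_rule("fixed_weights", w_s = 0.1, w_f = 0.9))
  rates <- rbind(
    data.frame(neuron_id = pop$id, condition_id = "bi", rate = resp$R),
    data.frame(neuron_id = pop$id, condition_id = "slower", rate = resp$R_s),
    data.frame(neuron_id = pop$id, condition_id = "faster", rate = resp$R_f))
  trials <- generate_poisson_trials(rates, n_trials = 1000, seed = 8)

  res <- split_trial_regression(trials, n_repeats = 10, seed = 2)
  # with many trials the split-trial slope matches the generative weight
  expect_lt(abs(res$mean_slope - 0.9), 0.02)
  # and the all-trials regression slope
  rate <- trials$spike_count / trials$duration
  mean_by <- function(cond) {
    keep <- trials$condition_id == cond
    tapply(rate[keep], trials$neuron_id[keep], mean)
  }
  allfit <- estimate_weights_regression(mean_by("bi")[pop$id],
                                        mean_by("slower")[pop$id],
                                        mean_by("faster")[pop$id])
  expect_lt(abs(res$mean_slope - allfit$slope), 0.02)
  # determinism
  res2 <- split_trial_regression(trials, n_repeats = 10, seed = 2)
  expect_identical(res$slopes, res2$slopes)
})
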