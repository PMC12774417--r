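test_that("log-Gaussian tuning has the stated form and limits", {
  neu <- fixture_neuron(pref = 10, peak = 50, base = 5, width = 1)
  expect_equal(tuning_response(neu, 10), 50)
  expect_equal(tuning_response(neu, 10 * exp(1)), 5 + 45 * exp(-1 / 2))
  # baseline limits at extreme speeds
  expect_lt(abs(tuning_response(neu, 1e-6) - 5), 1e-6)
  expect_lt(abs(tuning_response(neu, 1e8) - 5), 1e-6)
  expect_error(tuning_response(neu, -1), "positive")
  # the maximum is at the preferred speed
  v <- exp(seq(log(1.25), log(80), length.out = 501))
  expect_equal(v[which.max(tuning_response(neu, v))], 10, tolerance = 0.01)
})

test_that("population generation is deterministic, respects the distribution, and peaks near 20 deg/s", {
  pop <- make_population(100, seed = 1)
  expect_identical(pop, fixture_population())
  expect_equal(nrow(pop), 100)
  expect_true(all(pop$preferred_speed >= 1.25 & pop$preferred_speed <= 80))
  expect_true(all(pop$peak_rate > pop$baseline_rate))
  expect_true(all(pop$baseline_rate >= 0))

  # point mass
  one <- make_population(1, pref_dist = list(kind = "point", at = 10), seed = 99)
  expect_equal(one$preferred_speed, 10)
  expect_error(make_population(1, pref_dist = list(kind = "point", at = 100)),
               "support")

  # different seeds give different orderings but the same distribution
  a <- make_population(1000, seed = 1)
  b <- make_population(1000, seed = 2)
  expect_false(identical(a$preferred_speed, b$preferred_speed))
  ks <- suppressWarnings(
    stats::ks.test(log(a$preferred_speed), log(b$preferred_speed)))
  expect_gt(ks$p.value, 0.01)

  # population-average tuning attains its maximum between 10 and 40 deg/s
  for (s in 1:3) {
    p <- make_population(100, seed = s)
    v <- exp(seq(log(1.25), log(80), length.out = 301))
    peak <- v[which.max(colMeans(tuning_response(p, v)))]
    expect_gt(peak, 10)
    expect_lt(peak, 40)
  }
})

test_that("bi-speed responses follow the encoding rule exactly", {
  pop <- fixture_population()
  cond <- bispeed_condition(2.5, 10)
  R_s <- tuning_response(pop, 2.5)
  R_f <- tuning_response(pop, 10)

  # faster-component-take-all
  fta <- make_bispeed_responses(pop, cond, encoding_rule("fixed_weights",
                                                         w_s = 0, w_f = 1))
  expect_equal(fta$R, R_f)
  # averaging
  avg <- make_bispeed_responses(pop, cond, encoding_rule("average"))
  expect_equal(avg$R, (R_s + R_f) / 2)
  # symmetric normalization pool reduces to averaging
  nrm <- make_bispeed_responses(pop, cond,
    encoding_rule("normalization", n = 2, sigma = 0, alpha = 1, c = 0,
                  S_s = 50, S_f = 50))
  expect_equal(nrm$R, (R_s + R_f) / 2, tolerance = 1e-12)

  expect_error(make_bispeed_responses(pop, bispeed_condition(0.5, 10),
                                      encoding_rule("average")), "within")
  expect_error(encoding_rule("nonsense"))
  expect_error(encoding_rule("normalization", n = 500, sigma = 1, alpha = 1))
})

test_that("weights recovered from generated responses equal the rule's weights", {
  # the per-neuron recovery identity assumes the rule's weights sum to
  # one, so it applies to the weighted-average family of rules
  pop <- fixture_population()
  cond <- bispeed_condition(5, 20)
  rules <- list(
    encoding_rule("fixed_weights", w_s = 0.35, w_f = 0.65),
    encoding_rule("average"),
    encoding_rule("random_weights", seed = 4)
  )
  for (rule in rules) {
    resp <- make_bispeed_responses(pop, cond, rule)
    w <- component_weights(resp$R, resp$R_s, resp$R_f, tol = 1e-6)
    ok <- w$defined
    expect_lt(max(abs(w$w_f[ok] - resp$w_f[ok])), 1e-9)
    expect_lt(max(abs(w$w_s[ok] - resp$w_s[ok])), 1e-9)
  }
  # the normalization rule's weights do not sum to one; the generated
  # responses still satisfy R = w_s R_s + w_f R_f with its own weights
  nr <- make_bispeed_responses(pop, cond,
    encoding_rule("normalization", n = 4.13, sigma = 123, alpha = 1.57,
                  c = 0))
  expect_lt(max(abs(nr$R - (nr$w_s * nr$R_s + nr$w_f * nr$R_f))), 1e-9)
})

test_that("Poisson trials have the right moments and are reproducible", {
  # zero rate gives zero counts
  z <- generate_poisson_trials(c(a = 0), n_trials = 50, seed = 1)
  expect_true(all(z$spike_count == 0))

  t1 <- generate_poisson_trials(c(a = 40), n_trials = 10000, duration = 0.5,
                                seed = 7)
  m <- mean(t1$spike_count)
  se <- sqrt(20 / 10000)
  expect_lt(abs(m - 20), 3 * se)
  # variance/mean ratio near 1
  expect_lt(abs(var(t1$spike_count) / m - 1), 0.05)
  # determinism
  t2 <- generate_poisson_trials(c(a = 40), n_trials = 10000, duration = 0.5,
                                seed = 7)
  expect_identical(t1, t2)
  expect_error(generate_poisson_trials(c(a = -1), 10), "nonnegative")
})

test_that("trial and response tables round-trip through CSV", {
  tt <- generate_poisson_trials(c(n1 = 10, n2 = 30), n_trials = 5, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(back$spike_count, tt$spike_count)
  expect_error(read_trial_table(textConnection("a,b\n1,2")), "columns")
})
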