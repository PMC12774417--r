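# speedmix

Encoding and decoding of multiple motion speeds in neural populations.

When two overlapping dot fields move at different speeds, each
speed-tuned neuron in visual cortex (e.g. macaque area MT) emits a single
firing rate. `speedmix` implements the full analysis chain for asking how
that rate encodes both speeds and how the speeds can be read back out of
a population:

* **Component-weight estimation.** The bi-speed response is modeled as a
  weighted average of the component responses,
  `R = w_s R_s + w_f R_f` with `w_s + w_f = 1`; the faster-component
  weight is estimated as the slope of the population regression
  `(R − R_s) = k (R_f − R_s) + b`. Controls: a random-weight simulation
  (`R_e = a R_f + (1 − a) R_s`, `a ~ U(0,1)`, 1000 repetitions, mean
  slope 0.5) with a percentile bootstrap, and a split-trial regression
  that removes the shared `R_s` term.
* **Model fits for bi-directional stimuli.** A linear weighted sum
  `R_bi = w_s R_s(θ1) + w_f R_f(θ2) + c`, and a divisive-normalization
  model in which the weights are set by a speed-tuned *weighting pool*:
  `w_s = S_s^n / (S_s^n + α S_f^n + σ)`,
  `w_f = S_f^n / (S_s^n + α S_f^n + σ)`. Fit quality is percent variance
  explained, `PV = 100 (1 − SSE/SST)`.
* **Pseudo-population responses.** Per-neuron responses normalized by the
  maximum of the `p = 0.93` smoothing-spline tuning fit (csaps
  convention, implemented in the package), plotted against ln preferred
  speed and smoothed onto a 121-point log-uniform grid from 1.25 to
  80 deg/s.
* **Classifier discrimination.** Lasso-logistic linear classification of
  Poisson-resampled population responses (200 trials/class, 40-fold
  cross-validation), scored as d′.
* **Two-speed decoding.** A constrained decoder that finds the one- or
  two-point speed probability distribution whose estimated population
  response `spEP` best matches the observed `spRP`
  (`OF = −Σ [spEP − spRP]²`), via an exhaustive single-speed scan plus a
  center hill-climb over speed separations of 2–96 grid steps with
  weights on a 0.01 lattice; readouts classify as single/two by the 0.7
  weight-gap rule, and decode-based discrimination uses a 1.3x
  separation threshold.
* **Psychometrics.** d′ with a finite modified formula at extreme rates,
  and 3AFC accounting that splits "no two-speeds" reports evenly between
  hits and false alarms.

A synthetic-population generator (log-Gaussian speed tuning, preferred
speeds log-normal around 18 deg/s so the population-average tuning peaks
near 20 deg/s, von Mises direction tuning, independent Poisson trials
over a 500 ms window) makes the whole pipeline runnable and testable
without recordings.

## Worked example

```r
library(speedmix)

pop  <- make_population(100, seed = 1)          # synthetic MT-like sample
cond <- bispeed_condition(2.5, 10)              # 4x speed separation

# noise-free bi-speed responses with a strong faster-speed bias
resp <- make_bispeed_responses(pop, cond,
          encoding_rule("fixed_weights", w_s = 0.17, w_f = 0.83))
estimate_weights_regression(resp$R, resp$R_s, resp$R_f)
#> Faster-component weight (regression slope): 0.830 +/- 0.000 (95% CI)
#> Intercept: -0.00 spikes/s   R^2: 1.000   n = 100 neurons

ctrl <- random_weight_control(resp$R_s, resp$R_f, n_reps = 1000, seed = 1)
ctrl$mean_slope                                  # 0.501 — the 0.5 null
bootstrap_compare(0.83, ctrl$slopes)             # 0.000999 — bias is real

# decode two speeds back out of a population response
tun   <- fit_tuning_set(pop)
setup <- decoder_setup(tun)
bi <- make_bispeed_responses(pop, bispeed_condition(5, 20),
                             encoding_rule("average"))
decode(setup, responses = setNames(bi$R, pop$id))
#> Decoded two-speed readout: 5.548, 20.71 deg/s (weights 0.54, 0.46), OF = -0.00597
```

The regression recovers the generative faster-component weight exactly
(slope 0.830, intercept 0); the random-weight control confirms that a
slope this far above 0.5 cannot arise from the shared-term artifact
(bootstrap p ≈ 0.001). The decoder, given only the population response
to the 5/20 deg/s mixture, reads out two speeds within a few percent of
the true components with near-equal weights, and neither readout is a
boundary artifact.

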