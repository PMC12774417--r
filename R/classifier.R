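#' Protocol for classifier-based discrimination
#'
#' @param n_trials_per_class Poisson trials generated per stimulus class
#'   (default 200); must be divisible by `n_folds`.
#' @param n_folds cross-validation folds (default 40; each fold is the
#'   test set exactly once).
#' @param lambda L1 (lasso) penalty of the logistic classifier. The
#'   default `NULL` uses `1 / n_train`, a weak penalty; the quantity under
#'   test throughout the package is the ordering of d-prime across
#'   conditions, which is insensitive to this choice.
#' @param duration trial window in seconds (default 0.5).
#' @param seed integer seed.
#' @return list of class `"classifier_protocol"`.
#' @export
classifier_protocol <- function(n_trials_per_class = 200L, n_folds = 40L,
                                lambda = NULL, duration = 0.5, seed = 1L) {
  if (n_trials_per_class %% n_folds != 0)
    stop("n_trials_per_class must be divisible by n_folds")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_folds = as.integer(n_folds), lambda = lambda,
                 duration = duration, seed = as.integer(seed)),
            class = "classifier_protocol")
}

#' Cross-validated discrimination of bi-speed vs single-speed responses
#'
#' Trains an L1-regularized logistic (lasso) linear classifier to decide
#' whether a population response was elicited by a bi-speed stimulus or by
#' a single speed. Trial responses are generated as independent Poisson
#' spike counts around each neuron's trial-averaged rate (500 ms window)
#' and normalized by the neuron's fitted maximum rate, so the classifier
#' sees per-neuron normalized responses. Trials are partitioned into
#' `n_folds` folds; the classifier is trained on all but one fold and
#' tested on the held-out fold, rotating so every fold is tested exactly
#' once. Hits are bi-speed trials classified as bi-speed; false alarms are
#' single-speed trials classified as bi-speed; performance is the modified
#' d-prime.
#'
#' @param rates_bi,rates_single trial-averaged spikes/s per neuron for the
#'   two stimulus classes (named by neuron id, same neuron set).
#' @param max_rates per-neuron normalization divisors (fitted tuning-curve
#'   maxima, named by neuron id).
#' @param protocol a [classifier_protocol()].
#' @return list of class `"discrimination_result"`: `hit_rate`,
#'   `false_alarm_rate`, `d_prime`, `per_fold_accuracy`, `fold_id`.
#' @export
run_discrimination <- function(rates_bi, rates_single, max_rates,
                               protocol = classifier_protocol()) {
  ids <- names(rates_bi)
  if (is.null(ids) || !setequal(ids, names(rates_single)) ||
      !all(ids %in% names(max_rates)))
    stop("rates_bi, rates_single and max_rates must cover the same neurons")
  rates_single <- rates_single[ids]
  max_rates <- max_rates[ids]
  nt <- protocol$n_trials_per_class
  nf <- protocol$n_folds
  dur <- protocol$duration

  set.seed(protocol$seed)
  sim_class <- function(rates) {
    counts <- matrix(stats::rpois(nt * length(rates),
                                  rep(rates, each = nt) * dur), nrow = nt)
    sweep(counts / dur, 2, max_rates, "/")
  }
  X <- rbind(sim_class(rates_bi), sim_class(rates_single))
  yv <- factor(rep(c("bi", "single"), each = nt), levels = c("single", "bi"))
  # fold labels are assigned per class so folds stay class-balanced
  fold <- c(sample(rep(seq_len(nf), length.out = nt)),
            sample(rep(seq_len(nf), length.out = nt)))

  pred <- character(nrow(X))
  acc <- numeric(nf)
  for (f in seq_len(nf)) {
    test <- fold == f
    lam <- protocol$lambda
    if (is.null(lam)) lam <- 1 / sum(!test)
    fit <- glmnet::glmnet(X[!test, , drop = FALSE], yv[!test],
                          family = "binomial", alpha = 1,
                          lambda = c(5, 1, 0.2, 0.04, lam) * lam)
    p <- stats::predict(fit, X[test, , drop = FALSE], s = lam,
                        type = "class")
    pred[test] <- as.character(p)
    acc[f] <- mean(pred[test] == as.character(yv[test]))
  }
  hit <- mean(pred[yv == "bi"] == "bi")
  fa <- mean(pred[yv == "single"] == "bi")
  structure(list(hit_rate = hit, false_alarm_rate = fa,
                 d_prime = dprime(hit, fa),
                 per_fold_accuracy = acc, fold_id = fold),
            class = "discrimination_result")
}

#' Classifier discrimination for a synthetic bi-speed condition
#'
#' Convenience wrapper tying the synthetic generator, pseudo-population
#' normalization and classifier together: builds the bi-speed responses
#' under an encoding rule, the single log-mean-speed responses from the
#' tuning curves, and runs [run_discrimination()].
#'
#' @param population a `neuron_population`.
#' @param tuning its `"tuning_set"` ([fit_tuning_set()]).
#' @param condition a [bispeed_condition()].
#' @param rule an [encoding_rule()] for the bi-speed responses.
#' @param protocol a [classifier_protocol()].
#' @return a `"discrimination_result"`.
#' @export
discriminate_condition <- function(population, tuning, condition, rule,
                                   protocol = classifier_protocol()) {
  bi <- make_bispeed_responses(population, condition, rule)
  rates_bi <- stats::setNames(bi$R, bi$neuron_id)
  rates_single <- stats::setNames(
    tuning_response(population, condition$log_mean_speed), population$id)
  max_rates <- vapply(tuning$curves, function(cu) cu$max_rate, numeric(1))
  run_discrimination(rates_bi, rates_single, max_rates, protocol)
}
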