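#' Discriminability index d-prime
#'
#' `d' = qnorm(hit) - qnorm(fa)`. When either rate is exactly 0 or 1 the
#' standard formula is infinite, so a modified formula is used:
#' `d' = qnorm((100 h + 1)/102) - qnorm((100 f + 1)/102)`, which maps the
#' extremes to finite quantiles. With `method = "always"` the modified
#' formula is applied to all rates.
#'
#' @param hit,fa hit and false-alarm rates in \[0, 1\].
#' @param method `"extremes"` (default): modified formula only when a rate
#'   is exactly 0 or 1; `"always"`: modified formula for all rates.
#' @return finite d-prime.
#' @examples
#' dprime(0.84, 0.16)   # ~1.99
#' dprime(1, 0)         # 2 * qnorm(101/102)
#' @export
dprime <- function(hit, fa, method = c("extremes", "always")) {
  method <- match.arg(method)
  if (any(c(hit, fa) < 0) || any(c(hit, fa) > 1))
    stop("rates must be in [0, 1]")
  adj <- function(r) (100 * r + 1) / 102
  use_mod <- method == "always" | hit %in% c(0, 1) | fa %in% c(0, 1)
  h <- ifelse(use_mod, adj(hit), hit)
  f <- ifelse(use_mod, adj(fa), fa)
  stats::qnorm(h) - stats::qnorm(f)
}

#' d-prime for the 3AFC task with no-two-speeds reports
#'
#' In the three-alternative task, subjects may report that neither
#' interval contained two speeds ("no two-speeds choice", NTC). NTC trials
#' carry no discrimination information, so they are split evenly between
#' the hit and false-alarm tallies before the rates are computed: half the
#' NTC count is added to the hits (out of the bi-speed trials) and half to
#' the false alarms (out of the single-speed trials). Odd NTC counts
#' contribute fractional halves.
#'
#' @param hits correct bi-speed identifications (count).
#' @param false_alarms single-speed intervals called bi-speed (count).
#' @param ntc no-two-speeds reports (count).
#' @param n_bi_trials,n_single_trials presentations of each stimulus
#'   class. In the two-interval design every trial contains both classes,
#'   so both equal the trial count and `hits + false_alarms + ntc` sums to
#'   it as well.
#' @param method passed to [dprime()].
#' @return list of class `"psychometric_result"`: `hit_rate`,
#'   `false_alarm_rate`, `ntc_rate`, `d_prime`, `n_trials`.
#' @export
dprime_3afc <- function(hits, false_alarms, ntc, n_bi_trials,
                        n_single_trials, method = c("extremes", "always")) {
  if (any(c(hits, false_alarms, ntc) < 0)) stop("counts must be nonnegative")
  hr <- (hits + ntc / 2) / n_bi_trials
  fr <- (false_alarms + ntc / 2) / n_single_trials
  if (hr > 1 || fr > 1) stop("counts inconsistent with trial totals")
  n_trials <- max(n_bi_trials, n_single_trials)
  structure(list(hit_rate = hr, false_alarm_rate = fr,
                 ntc_rate = ntc / n_trials,
                 d_prime = dprime(hr, fr, method = method),
                 n_trials = n_trials),
            class = "psychometric_result")
}
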