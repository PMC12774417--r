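# Shared fixtures, built once per test run.

.fixtures <- new.env()

fixture_population <- function() {
  if (is.null(.fixtures$pop)) .fixtures$pop <- make_population(100, seed = 1)
  .fixtures$pop
}

fixture_tuning <- function() {
  if (is.null(.fixtures$tun))
    .fixtures$tun <- fit_tuning_set(fixture_population())
  .fixtures$tun
}

fixture_decoder <- function() {
  if (is.null(.fixtures$dec))
    .fixtures$dec <- decoder_setup(fixture_tuning())
  .fixtures$dec
}

# single synthetic neuron with hand-picked parameters
fixture_neuron <- function(pref = 10, peak = 50, base = 5, width = 1,
                           pd = 90, kappa = 2) {
  structure(data.frame(id = "n001", preferred_speed = pref,
                       tuning_width = width, peak_rate = peak,
                       baseline_rate = base, preferred_direction = pd,
                       direction_concentration = kappa,
                       stringsAsFactors = FALSE),
            class = c("neuron_population", "data.frame"))
}
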