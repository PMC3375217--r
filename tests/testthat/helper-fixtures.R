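# Shared small fixtures, all generated in code.

# a compact recording with clearly tuned units and a few onset units
small_recording <- function(n_units = 16, repetitions = 60, seed = 42,
                            ...) {
  generate_population(generator_config(
    n_units = n_units, repetitions = repetitions, seed = seed, ...))
}

# units table for fully controlled ground truth
unit_row <- function(unit_id, A, B, phi, rmax, kappa, lam,
                     is_onset = FALSE) {
  data.frame(unit_id = unit_id, latency_A = A, latency_B = B,
             pref_phi = phi, evoked_rate_max = rmax, rate_kappa = kappa,
             spont_rate = lam, is_onset = is_onset)
}

# exponential first-event density mass on a bin grid (rate in spikes/s)
exp_bin_mass <- function(rate, t_max, bin_ms) {
  edges <- seq(0, t_max, by = bin_ms)
  r <- rate / 1000
  exp(-r * edges[-length(edges)]) - exp(-r * edges[-1])
}
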