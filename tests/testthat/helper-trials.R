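# Shared fixtures: all synthetic, built in code.

noiseless_scenario <- function(...) {
  strike_scenario(noise_sd_force = 0, noise_sd_position = 0, ...)
}

# A walled direct-profile trial with a half-sine fore-aft pulse and a
# constant-body-weight vertical channel.
half_sine_trial <- function(fa_bw = 0.64, v_extra_bw = 0, mass = 0.5863,
                            window = c(0.15, 0.27)) {
  meta <- trial_meta(setup = "walled", mass = mass)
  bw <- mass * meta$g
  dur <- window[2] - window[1]
  generate_direct_profile_trial(
    fa = force_profile("half_sine", amplitude = fa_bw * bw,
                       onset = window[1], duration = dur),
    vertical = if (v_extra_bw > 0)
      force_profile("half_sine", amplitude = v_extra_bw * bw,
                    onset = window[1], duration = dur, baseline = bw)
    else force_profile("constant", amplitude = 0, baseline = bw,
                       onset = 0, duration = window[2] + window[1]),
    window = window, meta = meta)
}
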