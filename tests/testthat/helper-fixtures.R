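# Shared fixtures: all synthetic, built in code.

std_light <- function() light_protocol(uv_ms = c(100, 150), blue_ms = c(200, 250))

# fast-settling kinetics: the UV epoch window (125-150 ms) then sits at the
# cis photostationary plateau, so epoch-averaged conductances equal g_cis
fast_kinetics <- function(g_trans = 1, g_cis = 7.5)
  photoswitch_kinetics(g_trans, g_cis, tau1_ms = 0.5, tau2_ms = 2, frac1 = 0.7)

# acquisition chain of the hydrophobic-anion transient recordings
tpb_nf <- function(noise_sd_pA = 0)
  noise_filter_spec(noise_sd_pA = noise_sd_pA, filter_cutoff_kHz = 10,
                    series_resistance_MOhm = 2, membrane_capacitance_pF = 100)

# one UV/blue replicate: synthesize, reduce both epochs, fit
simulate_uv_blue_fits <- function(seed, g_trans = 1, g_cis = 7.5,
                                  noise_sd_pA = 2, dt_ms = 0.25) {
  ss <- synthesize_sweeps(step_protocol(dt_ms = dt_ms), std_light(),
                          fast_kinetics(g_trans, g_cis),
                          nf = noise_filter_spec(noise_sd_pA = noise_sd_pA),
                          seed = seed)
  list(uv = fit_supralinear(build_iv(ss, c(125, 150), epoch = "uv")),
       blue = fit_supralinear(build_iv(ss, c(225, 250), epoch = "blue")))
}
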