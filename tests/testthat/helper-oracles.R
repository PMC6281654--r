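# Independent oracles and small fixture builders shared across tests.

c_cm_ps <- beatmap::speed_of_light_cm_ps()

# brute-force harmonic state count: enumerate every quantum-number tuple
# with total energy <= e_max (independent of the Beyer-Swinehart fold)
brute_force_nstates <- function(freqs, e_max) {
  if (!length(freqs)) return(1L)
  grids <- lapply(freqs, function(f) seq.int(0L, floor(e_max / f)))
  tup <- as.matrix(expand.grid(grids))
  sum(drop(tup %*% freqs) <= e_max + 1e-9)
}

# brute-force level energies (for windowed density oracles)
brute_force_energies <- function(freqs, e_max) {
  grids <- lapply(freqs, function(f) seq.int(0L, floor(e_max / f)))
  tup <- as.matrix(expand.grid(grids))
  e <- drop(tup %*% freqs)
  e[e <= e_max + 1e-9]
}

# all pairwise level gaps of a wavepacket (the beat-frequency oracle)
pairwise_gaps <- function(energies) {
  sort(unique(as.vector(stats::dist(energies))))
}

# noiseless damped-beat transient via the kinetic model
make_beat_transient <- function(t, freqs, amps, damp_ps, tau_ps = 20,
                                irf = 0.1, phases = 0) {
  m <- beatmap::beat_fit_model(
    data.frame(amplitude = 1, lifetime_ps = tau_ps),
    data.frame(amplitude = amps, freq_cm1 = freqs,
               phase_rad = rep_len(phases, length(freqs)),
               damp_ps = damp_ps, group = 1L),
    irf_fwhm_ps = irf)
  beatmap::model_eval(m, t)
}
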